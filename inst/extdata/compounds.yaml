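# IKur inhibitor kinetic library.
# tau_onset: block development at depolarized voltages (ms)
# tau_recovery: unblock at hyperpolarized voltages (ms)
# '#5' is a tonic (state-independent) 50% block.
- name: "#1"
  tau_onset: 5
  tau_recovery: 1000
  properties: fast onset, slow recovery
- name: "#2"
  tau_onset: 16
  tau_recovery: 238
  properties: fast onset, fast recovery
- name: "#3"
  tau_onset: 100
  tau_recovery: 16000
  properties: slow onset, slow recovery
- name: "#4"
  tau_onset: 200
  tau_recovery: 250
  properties: slow onset, fast recovery
- name: "#5"
  tonic_level: 0.5
  properties: tonic block
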