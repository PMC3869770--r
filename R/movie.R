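# Self-describing movie container for tissue voltage fields.

#' Voltage-field movie container
#'
#' A time-stamped stack of membrane-voltage frames on a regular grid, with
#' optional sodium-inactivation (h) frames and precomputed summary series
#' (refractory fraction, pseudo-ECG).  All analysis stages
#' ([detect_phase_singularities()], [pseudo_ecg()], [refractory_fraction()],
#' [dominant_frequency()]) consume this container, whether it was produced by
#' the monodomain solver or by a synthetic fixture generator.
#'
#' @param vm numeric array `nx x ny x n_frames` of membrane voltage (mV).
#' @param t frame times (ms), strictly increasing, one per frame.
#' @param dx node spacing (mm).
#' @param h optional array of the INa inactivation gate, same shape as `vm`.
#' @param D optional effective conductivity (mm^2/ms) used to scale the
#'   diffusive source current in [pseudo_ecg()].
#' @param series optional list of precomputed series (`t`, `refractory_pct`,
#'   `ecg`) sampled by the solver at finer cadence than the frames.
#' @param meta named list of provenance attributes (condition, compound,
#'   protocol, ground truth for fixtures, ...).
#' @return an object of class `wave_movie`.
#' @export
wave_movie <- function(vm, t, dx, h = NULL, D = NULL, series = NULL,
                       meta = list()) {
  stopifnot(length(dim(vm)) == 3, dim(vm)[3] == length(t),
            all(diff(t) > 0), dx > 0)
  if (!is.null(h)) stopifnot(identical(dim(h), dim(vm)))
  structure(list(vm = vm, t = t, dx = dx, h = h, D = D,
                 series = series, meta = meta),
            class = "wave_movie")
}

#' @export
print.wave_movie <- function(x, ...) {
  d <- dim(x$vm)
  cat(sprintf("<wave_movie> %d x %d nodes (dx %g mm), %d frames, t = %g..%g ms\n",
              d[1], d[2], x$dx, d[3], x$t[1], x$t[length(x$t)]))
  if (length(x$meta)) {
    flat <- x$meta[vapply(x$meta, function(m) is.atomic(m) && length(m) == 1, TRUE)]
    if (length(flat))
      cat(" ", paste(names(flat), unlist(flat), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read/write a movie container
#'
#' Movies are serialized with their full attribute set (spacing, frame times,
#' metadata, summary series) so a written file is self-describing.
#'
#' @param movie a [wave_movie()].
#' @param path file path.
#' @return `read_movie` returns the `wave_movie`; `write_movie` returns
#'   `path` invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "wave_movie"))
  saveRDS(movie, path)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "wave_movie")) stop("not a wave_movie file: ", path)
  m
}
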