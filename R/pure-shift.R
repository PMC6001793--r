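#' @title Pure shift interferogram reconstruction
#' @description Concatenates data chunks from a pseudo-2D interferogram
#'   acquisition into a single homodecoupled 1D FID.
#' @name pure-shift
NULL

#' Pure shift reconstruction parameters
#'
#' `drop_points` applies to every chunk including the first; `first_chunk`
#' counts the points kept from the first chunk after dropping.
#'
#' @param chunks number of increments used.
#' @param chunk_points data points kept per chunk.
#' @param first_chunk points kept from the first chunk
#'   (<= `chunk_points`).
#' @param drop_points points discarded from the start of each chunk.
#' @param chunk_duration optional chunk duration, s; when given with a
#'   dwell it must satisfy `chunk_points = round(chunk_duration / dwell)`.
#' @export
pureshift_params <- function(chunks, chunk_points, first_chunk = chunk_points,
                             drop_points = 0, chunk_duration = NULL) {
  if (chunks < 1L) stop_data("chunks must be >= 1")
  if (drop_points < 0) stop_data("drop_points must be >= 0")
  if (first_chunk > chunk_points) stop_data("first_chunk must be <= chunk_points")
  structure(list(chunks = as.integer(chunks), chunk_points = as.integer(chunk_points),
                 first_chunk = as.integer(first_chunk),
                 drop_points = as.integer(drop_points),
                 chunk_duration = chunk_duration),
            class = "pureshift_params")
}

#' Reconstruct a 1D pure shift FID from interferogram raw data
#'
#' output = concat(inc_1[drop + 1 .. drop + first_chunk],
#' inc_2[drop + 1 .. drop + chunk_points], ..., inc_chunks[...]); the output
#' length is `first_chunk + (chunks - 1) * chunk_points` and the dwell is
#' preserved. Parameters default to those stored with the raw data
#' (`meta$pureshift`, as written by [make_pureshift_raw()] and the readers).
#'
#' @param raw a [fid_set()] with at least `params$chunks` increments.
#' @param params a [pureshift_params()] (or a plain list with the same
#'   fields); defaults to `raw$meta$pureshift`.
#' @return A single-increment [fid_set()].
#' @export
ps_reconstruct <- function(raw, params = NULL) {
  if (!inherits(raw, "fid_set")) stop_data("ps_reconstruct expects a fid_set")
  if (is.null(params)) params <- raw$meta$pureshift
  if (is.null(params)) stop_config("no pure shift parameters given or stored with the data")
  if (!inherits(params, "pureshift_params")) params <- do.call(pureshift_params, params[
    intersect(names(params), c("chunks", "chunk_points", "first_chunk",
                               "drop_points", "chunk_duration"))])
  if (!is.null(params$chunk_duration)) {
    expected <- as.integer(round(params$chunk_duration / raw$dwell))
    if (expected != params$chunk_points)
      stop_config("chunk_duration/dwell (%d points) disagrees with chunk_points (%d)",
                  expected, params$chunk_points)
  }
  if (nrow(raw$data) < params$chunks)
    stop_data("raw data has %d increments but %d chunks requested", nrow(raw$data), params$chunks)
  np <- ncol(raw$data)
  pieces <- vector("list", params$chunks)
  for (i in seq_len(params$chunks)) {
    keep <- if (i == 1L) params$first_chunk else params$chunk_points
    need <- params$drop_points + keep
    if (np < need)
      stop_data("increment %d has %d points; %d needed (drop %d + keep %d)",
                i, np, need, params$drop_points, keep)
    pieces[[i]] <- raw$data[i, params$drop_points + seq_len(keep)]
  }
  out <- matrix(unlist(pieces), nrow = 1)
  fid_set(out, dwell = raw$dwell, sfrq = raw$sfrq, ref_offset_hz = raw$ref_offset_hz,
          meta = c(raw$meta[setdiff(names(raw$meta), "pureshift")],
                   list(pureshift_reconstructed = TRUE)))
}
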