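#' @title Internal save format and result exporters
#' @description A simple self-describing on-disk format (JSON metadata plus
#'   binary or human-readable ASCII data) for FID and spectrum sets, and
#'   CSV/JSON exporters for analysis results.
#' @name io-internal
NULL

INTERNAL_FORMAT_VERSION <- 1L

axis_to_meta <- function(a) list(kind = a$kind, values = a$values, label = a$label)

#' Write a data set in the internal format
#'
#' Creates a directory with `meta.json` (all acquisition fields, axes,
#' phase state) and the complex data as interleaved real/imag pairs:
#' IEEE-754 double little-endian in `data.bin` (binary mode, bit-exact
#' round trip) or one "real imag" pair per line in `data.txt` (ASCII mode,
#' 17 significant digits).
#'
#' @param x a [fid_set()] or [spectrum_set()].
#' @param dir output directory (created).
#' @param mode `"binary"` or `"ascii"`.
#' @return `dir`, invisibly.
#' @export
write_internal <- function(x, dir, mode = c("binary", "ascii")) {
  mode <- match.arg(mode)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  type <- if (inherits(x, "fid_set")) "fid_set"
          else if (inherits(x, "spectrum_set")) "spectrum_set"
          else stop_data("write_internal expects a fid_set or spectrum_set")
  meta <- list(version = INTERNAL_FORMAT_VERSION, type = type, mode = mode,
               n_increments = nrow(x$data), n_points = ncol(x$data),
               sfrq = x$sfrq, ref_offset_hz = x$ref_offset_hz,
               arrays = lapply(x$arrays, axis_to_meta))
  if (type == "fid_set") {
    meta$dwell <- x$dwell
  } else {
    meta$axis_hz_first <- x$axis_hz[1]
    meta$axis_hz_step <- x$axis_hz[2] - x$axis_hz[1]
    meta$ph0 <- x$ph0
    meta$ph1 <- x$ph1
    meta$pivot_hz <- x$pivot_hz
    meta$mask_false <- which(!x$mask)
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  inter <- as.numeric(rbind(as.vector(t(Re(x$data))), as.vector(t(Im(x$data)))))
  if (mode == "binary") {
    con <- file(file.path(dir, "data.bin"), "wb")
    writeBin(inter, con, size = 8L, endian = "little")
    close(con)
  } else {
    pairs <- matrix(inter, ncol = 2L, byrow = TRUE)
    writeLines(sprintf("%.17g %.17g", pairs[, 1], pairs[, 2]), file.path(dir, "data.txt"))
  }
  invisible(dir)
}

#' Read a data set in the internal format
#'
#' Inverse of [write_internal()]; `write_internal` then `read_internal` is
#' the identity (bit-exact in binary mode).
#'
#' @param dir directory written by [write_internal()].
#' @return A [fid_set()] or [spectrum_set()] per the stored type.
#' @export
read_internal <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop_format("no meta.json in %s", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$version) || meta$version != INTERNAL_FORMAT_VERSION)
    stop_format("unsupported internal format version: %s", meta$version)
  n <- meta$n_increments * meta$n_points * 2L
  if (identical(meta$mode, "binary")) {
    con <- file(file.path(dir, "data.bin"), "rb")
    inter <- readBin(con, "double", n = n, size = 8L, endian = "little")
    close(con)
  } else {
    rows <- strsplit(readLines(file.path(dir, "data.txt"), warn = FALSE), "\\s+")
    inter <- as.numeric(unlist(rows))
  }
  if (length(inter) != n) stop_format("data length %d does not match metadata (%d)", length(inter), n)
  cvals <- complex(real = inter[c(TRUE, FALSE)], imaginary = inter[c(FALSE, TRUE)])
  data <- matrix(cvals, nrow = meta$n_increments, byrow = TRUE)
  arrays <- if (is.data.frame(meta$arrays)) {
    lapply(seq_len(nrow(meta$arrays)), function(i)
      increment_axis(meta$arrays$values[[i]], meta$arrays$kind[[i]], meta$arrays$label[[i]]))
  } else {
    lapply(meta$arrays, function(a) increment_axis(a$values, a$kind, a$label))
  }
  if (meta$type == "fid_set") {
    fid_set(data, dwell = meta$dwell, sfrq = meta$sfrq,
            ref_offset_hz = meta$ref_offset_hz, arrays = arrays)
  } else {
    fn <- meta$n_points
    axis_hz <- meta$axis_hz_first + meta$axis_hz_step * (seq_len(fn) - 1L)
    mask <- rep(TRUE, fn)
    if (length(meta$mask_false)) mask[unlist(meta$mask_false)] <- FALSE
    spectrum_set(data, axis_hz = axis_hz, sfrq = meta$sfrq,
                 ref_offset_hz = meta$ref_offset_hz, ph0 = meta$ph0, ph1 = meta$ph1,
                 pivot_hz = meta$pivot_hz, arrays = arrays, mask = mask)
  }
}

result_table <- function(x) {
  if (is.data.frame(x)) return(x)
  if (inherits(x, "peak_fit")) x <- list(x)
  if (is.list(x) && length(x) && inherits(x[[1]], "peak_fit")) {
    return(do.call(rbind, lapply(x, function(f) {
      d <- data.frame(position_ppm = f$position_ppm, amplitude = f$amplitude,
                      rss = f$rss, n_points_used = f$n_points_used)
      for (nm in names(f$params)) d[[nm]] <- f$params[[nm]]
      for (nm in names(f$se)) d[[paste0("se_", nm)]] <- f$se[[nm]]
      d
    })))
  }
  if (inherits(x, "component_decomposition")) {
    d <- data.frame(component = seq_along(x$params), param = x$params,
                    fraction_pct = x$fractions)
    names(d)[2] <- x$param_name
    return(d)
  }
  stop_data("no tabular export for class %s", paste(class(x), collapse = "/"))
}

#' Export analysis results
#'
#' Writes a deterministic, fully precise table (17 significant digits) for
#' a peak-fit list, a `component_decomposition`, or any data.frame.
#'
#' @param x result object.
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_results <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  d <- result_table(x)
  if (format == "csv") {
    d2 <- d
    for (j in seq_along(d2)) {
      if (is.numeric(d2[[j]])) d2[[j]] <- formatC(d2[[j]], format = "g", digits = 17)
    }
    utils::write.csv(d2, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(d, path, dataframe = "columns", digits = NA, auto_unbox = FALSE)
  }
  invisible(path)
}

#' Re-import an exported JSON result table
#'
#' @param path file written by [export_results(format = "json")].
#' @return data.frame equal to the exported table.
#' @export
import_results <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
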