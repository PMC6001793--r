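#' @title Bruker-format reader and fixture writer
#' @description Reads `fid`/`ser` + `acqus` directory trees (including
#'   `difflist`/`vdlist`/`vclist` increment lists and series of consecutively
#'   numbered 1D datasets) and writes byte-compatible fixtures for testing.
#' @name io-bruker
NULL

parse_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^##\\$?([A-Za-z0-9_]+)=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      val <- suppressWarnings(as.numeric(m[3]))
      out[[m[2]]] <- if (is.na(val)) m[3] else val
    }
  }
  out
}

parse_duration <- function(s) {
  # vdlist entries: plain seconds or with m/u suffix (milli/micro)
  s <- trimws(s)
  mult <- 1
  if (grepl("m$", s)) { mult <- 1e-3; s <- sub("m$", "", s) }
  else if (grepl("u$", s)) { mult <- 1e-6; s <- sub("u$", "", s) }
  else if (grepl("s$", s)) { s <- sub("s$", "", s) }
  as.numeric(s) * mult
}

read_increment_lists <- function(dir, n_inc) {
  arrays <- list()
  dl <- file.path(dir, "difflist")
  if (file.exists(dl)) {
    g <- as.numeric(readLines(dl, warn = FALSE))
    g <- g[is.finite(g)]
    arrays <- c(arrays, list(increment_axis(g, "gradient", "difflist (T/m)")))
  }
  vd <- file.path(dir, "vdlist")
  if (file.exists(vd)) {
    v <- vapply(readLines(vd, warn = FALSE), parse_duration, numeric(1), USE.NAMES = FALSE)
    v <- v[is.finite(v)]
    arrays <- c(arrays, list(increment_axis(v, "delay", "vdlist (s)")))
  }
  vc <- file.path(dir, "vclist")
  if (file.exists(vc)) {
    v <- as.numeric(readLines(vc, warn = FALSE))
    v <- v[is.finite(v)]
    arrays <- c(arrays, list(increment_axis(v, "counter", "vclist")))
  }
  arrays
}

read_bruker_one <- function(dir) {
  acqus_path <- file.path(dir, "acqus")
  if (!file.exists(acqus_path)) stop_format("no acqus in %s", dir)
  acqus <- parse_jcamp(acqus_path)
  need <- c("TD", "SW_h", "SFO1")
  for (k in need) if (is.null(acqus[[k]])) stop_format("acqus lacks ##$%s", k)
  td <- as.integer(acqus$TD)
  if (td %% 2L != 0L) stop_format("TD must be even (real/imag pairs)")
  byte_order <- if (!is.null(acqus$BYTORDA) && acqus$BYTORDA == 1) "big" else "little"
  dtypa <- if (is.null(acqus$DTYPA)) 0 else acqus$DTYPA  # absent -> int32 legacy default
  grpdly <- if (is.null(acqus$GRPDLY)) 0 else max(0, acqus$GRPDLY)
  nc <- if (is.null(acqus$NC)) 0 else acqus$NC
  n_inc <- 1L
  acqu2s_path <- file.path(dir, "acqu2s")
  if (file.exists(acqu2s_path)) {
    acqu2s <- parse_jcamp(acqu2s_path)
    if (!is.null(acqu2s$TD)) n_inc <- as.integer(acqu2s$TD)
  }
  data_path <- file.path(dir, if (file.exists(file.path(dir, "ser"))) "ser" else "fid")
  if (!file.exists(data_path)) stop_format("no fid or ser in %s", dir)
  bytes <- if (dtypa == 2) 8L else 4L
  what <- if (dtypa == 2) "double" else "integer"
  expected <- n_inc * td
  raw_size <- file.info(data_path)$size
  if (raw_size != expected * bytes)
    stop_format("%s has %d bytes; %d expected from TD=%d x %d increments",
                basename(data_path), raw_size, expected * bytes, td, n_inc)
  con <- file(data_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = what, n = expected, size = bytes, endian = byte_order)
  vals <- as.numeric(vals) * 2^nc
  m <- matrix(vals, nrow = n_inc, byrow = TRUE)
  cdata <- matrix(complex(real = t(m)[c(TRUE, FALSE), ], imaginary = t(m)[c(FALSE, TRUE), ]),
                  nrow = n_inc, byrow = TRUE)
  gd <- as.integer(round(grpdly))
  if (gd > 0L) cdata <- cdata[, -(seq_len(gd)), drop = FALSE]
  arrays <- read_increment_lists(dir, n_inc)
  arrays <- Filter(function(a) length(a$values) == n_inc, arrays)
  if (length(arrays) > 2L) arrays <- arrays[1:2]
  ref_offset <- if (is.null(acqus$O1)) 0 else acqus$O1
  fid_set(cdata, dwell = 1 / acqus$SW_h, sfrq = acqus$SFO1, ref_offset_hz = ref_offset,
          arrays = arrays, meta = list(source = dir, format = "bruker",
                                       byte_order = byte_order, dtypa = dtypa,
                                       group_delay = gd))
}

#' Read a Bruker dataset
#'
#' Reads `fid`/`ser` + `acqus` (and `acqu2s`, `difflist`, `vdlist`,
#' `vclist`). Data are deinterleaved real/imag pairs, byte order per
#' `BYTORDA`, type per `DTYPA` (absent: int32, scaled by `2^NC`);
#' `round(GRPDLY)` leading complex points are discarded. `dwell = 1/SW_h`,
#' `sfrq = SFO1`. A directory containing consecutively numbered 1D datasets
#' (`1`, `2`, ...) is read as an array; the datasets must share dwell and
#' sfrq.
#'
#' @param dir dataset directory.
#' @return A [fid_set()] (gradient/delay/counter lists become increment
#'   axes).
#' @export
read_bruker <- function(dir) {
  if (!dir.exists(dir)) stop_format("no such directory: %s", dir)
  if (file.exists(file.path(dir, "acqus"))) return(read_bruker_one(dir))
  subs <- list.dirs(dir, recursive = FALSE)
  nums <- suppressWarnings(as.integer(basename(subs)))
  subs <- subs[!is.na(nums)]
  nums <- nums[!is.na(nums)]
  if (!length(subs)) stop_format("no acqus and no numbered 1D datasets in %s", dir)
  subs <- subs[order(nums)]
  fids <- lapply(subs, read_bruker_one)
  dw <- vapply(fids, function(f) f$dwell, numeric(1))
  sf <- vapply(fids, function(f) f$sfrq, numeric(1))
  if (diff(range(dw)) > 1e-12 * dw[1] || diff(range(sf)) > 1e-9 * sf[1])
    stop_format("numbered datasets do not share dwell/sfrq")
  np <- min(vapply(fids, function(f) ncol(f$data), integer(1)))
  data <- do.call(rbind, lapply(fids, function(f) f$data[, seq_len(np), drop = FALSE]))
  fid_set(data, dwell = dw[1], sfrq = sf[1], ref_offset_hz = fids[[1]]$ref_offset_hz,
          arrays = list(increment_axis(seq_along(fids), "counter", "dataset number")),
          meta = list(source = dir, format = "bruker_series"))
}

#' Write a Bruker-format fixture
#'
#' Emits `acqus` (+ `acqu2s` for arrays), `fid`/`ser` and any increment
#' lists in the dialect [read_bruker()] expects. With `dtype = "int32"` the
#' data are scaled by a power-of-two `NC` exponent so the largest magnitude
#' fits in 31 bits (quantisation at most 0.5 LSB).
#'
#' @param fid a [fid_set()].
#' @param dir output directory (created).
#' @param byte_order `"little"` or `"big"` (`BYTORDA` 0/1).
#' @param dtype `"float64"` (`DTYPA` 2) or `"int32"` (`DTYPA` 0).
#' @param group_delay complex points of group delay to prepend as zeros
#'   (`GRPDLY`).
#' @return `dir`, invisibly.
#' @export
write_bruker_fixture <- function(fid, dir, byte_order = c("little", "big"),
                                 dtype = c("float64", "int32"), group_delay = 0) {
  byte_order <- match.arg(byte_order)
  dtype <- match.arg(dtype)
  if (!inherits(fid, "fid_set")) stop_data("write_bruker_fixture expects a fid_set")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gd <- as.integer(round(group_delay))
  data <- fid$data
  if (gd > 0L) data <- cbind(matrix(0 + 0i, nrow(data), gd), data)
  np <- ncol(data)
  td <- 2L * np
  n_inc <- nrow(data)
  # row-wise interleave: for each increment re1 im1 re2 im2 ...
  inter <- numeric(2L * np * n_inc)
  for (i in seq_len(n_inc)) {
    inter[(i - 1L) * td + seq_len(td)] <- as.numeric(rbind(Re(data[i, ]), Im(data[i, ])))
  }
  nc <- 0L
  if (dtype == "int32") {
    mx <- max(abs(inter), 1e-300)
    nc <- as.integer(ceiling(log2(mx / (2^30))))
    inter <- round(inter / 2^nc)
  }
  acqus <- c("##TITLE= fixture",
             sprintf("##$TD= %d", td),
             sprintf("##$SW_h= %.17g", 1 / fid$dwell),
             sprintf("##$SFO1= %.17g", fid$sfrq),
             sprintf("##$O1= %.17g", fid$ref_offset_hz),
             sprintf("##$BYTORDA= %d", if (byte_order == "big") 1L else 0L),
             sprintf("##$DTYPA= %d", if (dtype == "float64") 2L else 0L),
             sprintf("##$GRPDLY= %d", gd),
             sprintf("##$NC= %d", nc),
             "##END=")
  writeLines(acqus, file.path(dir, "acqus"))
  if (n_inc > 1L) {
    writeLines(c("##TITLE= fixture", sprintf("##$TD= %d", n_inc), "##END="),
               file.path(dir, "acqu2s"))
  }
  con <- file(file.path(dir, if (n_inc > 1L) "ser" else "fid"), "wb")
  if (dtype == "float64") {
    writeBin(inter, con, size = 8L, endian = byte_order)
  } else {
    writeBin(as.integer(inter), con, size = 4L, endian = byte_order)
  }
  close(con)
  for (a in fid$arrays) {
    file <- switch(a$kind, gradient = "difflist", delay = "vdlist", time = "vdlist",
                   counter = "vclist", NULL)
    if (!is.null(file)) {
      writeLines(formatC(a$values, format = "g", digits = 17), file.path(dir, file))
    }
  }
  invisible(dir)
}
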