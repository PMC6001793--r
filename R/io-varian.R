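#' @title Varian/Agilent-format reader and fixture writer
#' @description Reads `fid` + `procpar` directories (binary big-endian file
#'   and block headers; 16-bit int, 32-bit int and float32 storage) and
#'   writes byte-compatible fixtures.
#' @name io-varian
NULL

# status flag bits of the Varian file header
VAR_S_DATA <- 0x1L
VAR_S_SPEC <- 0x2L
VAR_S_32 <- 0x4L
VAR_S_FLOAT <- 0x8L
VAR_S_COMPLEX <- 0x10L

parse_procpar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    head <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(head) < 3L) { i <- i + 1L; next }
    name <- head[1]
    basictype <- suppressWarnings(as.integer(head[3]))
    i <- i + 1L
    if (i > length(lines)) break
    vals_line <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    nvals <- suppressWarnings(as.integer(vals_line[1]))
    if (is.na(nvals)) { i <- i + 1L; next }
    if (!is.na(basictype) && basictype == 2L) {
      # string values: one quoted value per line starting on this line
      vals <- character(nvals)
      vals[1] <- gsub("\"", "", paste(vals_line[-1], collapse = " "))
      for (k in seq_len(nvals - 1L)) {
        i <- i + 1L
        vals[k + 1L] <- gsub("\"", "", trimws(lines[i]))
      }
      out[[name]] <- vals
    } else {
      vals <- suppressWarnings(as.numeric(vals_line[-1]))
      while (length(vals) < nvals && i < length(lines)) {
        i <- i + 1L
        vals <- c(vals, suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])))
      }
      out[[name]] <- vals[seq_len(nvals)]
    }
    i <- i + 2L   # skip the trailing enumeration line
  }
  out
}

varian_axis_kind <- function(name) {
  if (grepl("^gzlvl", name)) "gradient"
  else if (name %in% c("d2", "vd", "tau")) "delay"
  else if (name %in% c("vc", "nt2", "bigtau")) "counter"
  else "generic"
}

#' Read a Varian/Agilent dataset
#'
#' Parses `procpar` and the binary `fid` (big-endian file/block headers).
#' Storage is decoded from the header status flags and `ebytes`: 16-bit
#' integer, 32-bit integer or float32. The arrayed parameter (any procpar
#' parameter with one value per block, e.g. a `gzlvl` gradient list) is
#' mapped to an increment axis. `dwell = 1/sw`, `sfrq = sfrq`.
#'
#' @param dir dataset directory containing `procpar` and `fid`.
#' @return A [fid_set()].
#' @export
read_varian <- function(dir) {
  pp_path <- file.path(dir, "procpar")
  fid_path <- file.path(dir, "fid")
  if (!file.exists(pp_path)) stop_format("no procpar in %s", dir)
  if (!file.exists(fid_path)) stop_format("no fid in %s", dir)
  pp <- parse_procpar(pp_path)
  for (k in c("sw", "sfrq")) if (is.null(pp[[k]])) stop_format("procpar lacks %s", k)
  con <- file(fid_path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 6L, size = 4L, endian = "big")
  names(hdr) <- c("nblocks", "ntraces", "np", "ebytes", "tbytes", "bbytes")
  vers_status <- readBin(con, "integer", n = 2L, size = 2L, endian = "big")
  status <- vers_status[2]
  nbheaders <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (hdr["np"] %% 2L != 0L) stop_format("np must be even")
  if (hdr["nblocks"] < 1L) stop_format("nblocks must be >= 1")
  is_float <- bitwAnd(status, VAR_S_FLOAT) != 0L
  is_32 <- bitwAnd(status, VAR_S_32) != 0L
  known <- bitwOr(bitwOr(bitwOr(VAR_S_DATA, VAR_S_SPEC), bitwOr(VAR_S_32, VAR_S_FLOAT)),
                  VAR_S_COMPLEX)
  if (bitwAnd(status, bitwNot(known)) != 0L)
    stop_format("unknown status flags in fid header: 0x%x", status)
  if (is_float && hdr["ebytes"] != 4L) stop_format("float data must have ebytes = 4")
  np <- hdr["np"]
  n_inc <- hdr["nblocks"] * hdr["ntraces"]
  data <- matrix(0 + 0i, n_inc, np / 2L)
  row <- 1L
  for (b in seq_len(hdr["nblocks"])) {
    for (h in seq_len(max(1L, nbheaders))) {
      readBin(con, "integer", n = 4L, size = 2L, endian = "big")  # scale,status,index,mode
      readBin(con, "integer", n = 1L, size = 4L, endian = "big")  # ctcount
      readBin(con, "numeric", n = 4L, size = 4L, endian = "big")  # lpval,rpval,lvl,tlt
    }
    for (tr in seq_len(hdr["ntraces"])) {
      vals <- if (is_float) {
        readBin(con, "numeric", n = np, size = 4L, endian = "big")
      } else if (is_32 || hdr["ebytes"] == 4L) {
        readBin(con, "integer", n = np, size = 4L, endian = "big")
      } else {
        readBin(con, "integer", n = np, size = 2L, endian = "big")
      }
      if (length(vals) < np) stop_format("fid file truncated in block %d", b)
      data[row, ] <- complex(real = vals[c(TRUE, FALSE)], imaginary = vals[c(FALSE, TRUE)])
      row <- row + 1L
    }
  }
  arrays <- list()
  skip <- c("sw", "sfrq", "np", "at", "fn", "tof")
  for (name in names(pp)) {
    v <- pp[[name]]
    if (is.numeric(v) && length(v) == n_inc && n_inc > 1L && !(name %in% skip)) {
      arrays <- list(increment_axis(v, varian_axis_kind(name), name))
      break
    }
  }
  fid_set(data, dwell = 1 / pp$sw[1], sfrq = pp$sfrq[1],
          ref_offset_hz = if (is.null(pp$reffrq_offset)) 0 else pp$reffrq_offset[1],
          arrays = arrays,
          meta = list(source = dir, format = "varian", status = status))
}

write_procpar_param <- function(name, values, basictype = 1L) {
  head <- sprintf("%s 1 %d 1e+30 -1e+30 0 2 2 0 1 64", name, basictype)
  vals <- paste(c(length(values), formatC(values, format = "g", digits = 17)), collapse = " ")
  c(head, vals, "0")
}

#' Write a Varian-format fixture
#'
#' Emits `procpar` and a big-endian binary `fid` with file and block
#' headers in the dialect [read_varian()] expects.
#'
#' @param fid a [fid_set()].
#' @param dir output directory (created).
#' @param dtype `"float32"`, `"int32"` or `"int16"` (integer storage rounds
#'   the values; scale the data beforehand).
#' @return `dir`, invisibly.
#' @export
write_varian_fixture <- function(fid, dir, dtype = c("float32", "int32", "int16")) {
  dtype <- match.arg(dtype)
  if (!inherits(fid, "fid_set")) stop_data("write_varian_fixture expects a fid_set")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_inc <- nrow(fid$data)
  np <- 2L * ncol(fid$data)
  ebytes <- switch(dtype, float32 = 4L, int32 = 4L, int16 = 2L)
  status <- bitwOr(VAR_S_DATA, VAR_S_COMPLEX)
  if (dtype == "float32") status <- bitwOr(status, VAR_S_FLOAT)
  if (dtype == "int32") status <- bitwOr(status, VAR_S_32)
  tbytes <- np * ebytes
  bbytes <- tbytes + 28L
  con <- file(file.path(dir, "fid"), "wb")
  writeBin(as.integer(c(n_inc, 1L, np, ebytes, tbytes, bbytes)), con, size = 4L, endian = "big")
  writeBin(as.integer(c(0L, status)), con, size = 2L, endian = "big")
  writeBin(1L, con, size = 4L, endian = "big")
  for (i in seq_len(n_inc)) {
    writeBin(as.integer(c(0L, status, i, 0L)), con, size = 2L, endian = "big")
    writeBin(0L, con, size = 4L, endian = "big")
    writeBin(numeric(4L), con, size = 4L, endian = "big")
    inter <- as.numeric(rbind(Re(fid$data[i, ]), Im(fid$data[i, ])))
    if (dtype == "float32") {
      writeBin(inter, con, size = 4L, endian = "big")
    } else {
      writeBin(as.integer(round(inter)), con, size = ebytes, endian = "big")
    }
  }
  close(con)
  pp <- c(write_procpar_param("sw", 1 / fid$dwell),
          write_procpar_param("sfrq", fid$sfrq),
          write_procpar_param("np", np))
  if (length(fid$arrays) == 1L) {
    a <- fid$arrays[[1]]
    name <- switch(a$kind, gradient = "gzlvl1", delay = "d2", time = "d2",
                   counter = "vc", "arrayed")
    pp <- c(pp, write_procpar_param(name, a$values))
  }
  writeLines(pp, file.path(dir, "procpar"))
  invisible(dir)
}
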