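#' Read and write NIfTI volumes
#'
#' Thin wrappers over RNifti preserving data and the voxel-to-world affine.
#'
#' @param vol 3D or 4D array.
#' @param grid a [grid_geometry()] supplying the affine.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_nifti_vol()` returns a list with `data` (array) and
#'   `affine`; writers return the path invisibly.
#' @export
write_nifti_vol <- function(vol, grid, path) {
  img <- RNifti::asNifti(vol)
  # RNifti normalises assigned xforms by the current pixdim, so set the
  # voxel dimensions first
  RNifti::pixdim(img) <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_vol
#' @export
read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), affine = unclass(RNifti::xform(img)))
}

#' Write / read a DWI series as NIfTI + FSL bvals/bvecs
#'
#' The bvec dialect is FSL style: `bvals` one white-space separated row of N
#' values, `bvecs` three rows of N (x, y, z components), directions in the
#' image-axis frame. On load, direction norms outside 1 +- 1e-3 are
#' renormalised with a warning; a bvals/bvecs length mismatch is an error.
#'
#' @param dwi a [dwi_series()].
#' @param basepath path without extension; writes `.nii.gz`, `.bval`,
#'   `.bvec`.
#' @export
write_dwi <- function(dwi, basepath) {
  write_nifti_vol(dwi$data, dwi$grid, paste0(basepath, ".nii.gz"))
  write_scheme(dwi$scheme, paste0(basepath, ".bval"), paste0(basepath, ".bvec"))
  invisible(basepath)
}

#' @rdname write_dwi
#' @param bval_path,bvec_path scheme file paths.
#' @param scheme a [gradient_scheme()].
#' @param delta,Delta,te PGSE timings (ms) to attach on read (not stored in
#'   the FSL format).
#' @export
write_scheme <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(t(scheme$dirs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 12), collapse = " ")), bvec_path)
  invisible(bval_path)
}

#' @rdname write_dwi
#' @export
read_scheme <- function(bval_path, bvec_path, delta = 35, Delta = 42,
                        te = 84) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(readLines(bvec_path), function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (length(rows) != 3)
    stop("bvec file must have exactly 3 rows", call. = FALSE)
  if (any(vapply(rows, length, 0L) != length(bvals)))
    stop("bvals/bvecs length mismatch", call. = FALSE)
  dirs <- t(do.call(rbind, rows))
  nrm <- sqrt(rowSums(dirs^2))
  dw <- bvals > 0
  off <- dw & abs(nrm - 1) > 1e-3
  if (any(off)) {
    warning(sprintf("%d b-vector(s) deviate from unit norm; renormalised",
                    sum(off)))
  }
  gradient_scheme(bvals, dirs, delta = delta, Delta = Delta, te = te)
}

#' @rdname write_dwi
#' @param nifti_path DWI image path.
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path, delta = 35,
                     Delta = 42, te = 84) {
  img <- read_nifti_vol(nifti_path)
  stopifnot(length(dim(img$data)) == 4)
  vox <- img$affine[1, 1]
  grid <- grid_geometry(dim(img$data)[1:3], vox_mm = abs(vox),
                        origin = img$affine[1:3, 4])
  grid$affine <- img$affine
  scheme <- read_scheme(bval_path, bvec_path, delta, Delta, te)
  dwi_series(img$data, grid, scheme)
}

#' Read and write TCK streamline files
#'
#' The MRtrix track-file dialect: a text header terminated by `END\n`,
#' then little-endian float32 coordinate triplets in world mm, one
#' NaN-triplet between streamlines and an Inf-triplet terminating the file.
#'
#' @param sl a `streamline_set`.
#' @param path file path.
#' @return `read_tck()` returns a `streamline_set` (seed bookkeeping is not
#'   stored in the format and is absent after a round trip).
#' @export
write_tck <- function(sl, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("mrtrix tracks",
           "datatype: Float32LE",
           sprintf("count: %d", length(sl$streamlines)),
           sprintf("step_size: %g", sl$step_mm))
  hdr_txt <- paste0(paste(hdr, collapse = "\n"), "\n")
  offset_line <- function(n) sprintf("file: . %d\nEND\n", n)
  # fixed-point iteration for the self-referential byte offset
  n <- nchar(hdr_txt, type = "bytes") + nchar(offset_line(0), type = "bytes")
  for (i in 1:3) n <- nchar(hdr_txt, type = "bytes") +
    nchar(offset_line(n), type = "bytes")
  writeChar(paste0(hdr_txt, offset_line(n)), con, eos = NULL)
  for (v in sl$streamlines) {
    writeBin(as.numeric(t(v)), con, size = 4, endian = "little")
    writeBin(as.numeric(rep(NaN, 3)), con, size = 4, endian = "little")
  }
  writeBin(as.numeric(rep(Inf, 3)), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_tck
#' @export
read_tck <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  end_marker <- as.raw(c(0x45, 0x4e, 0x44, 0x0a)) # "END\n"
  pos <- NULL
  for (i in seq_len(length(raw) - 3)) {
    if (all(raw[i:(i + 3)] == end_marker)) { pos <- i + 3; break }
  }
  if (is.null(pos)) stop("not a TCK file: missing END header terminator",
                         call. = FALSE)
  hdr <- strsplit(rawToChar(raw[1:pos]), "\n")[[1]]
  off_line <- grep("^file: \\.", hdr, value = TRUE)
  offset <- if (length(off_line) == 1)
    as.integer(sub("^file: \\. ", "", off_line)) else pos
  step <- grep("^step_size:", hdr, value = TRUE)
  step_mm <- if (length(step) == 1)
    as.numeric(sub("^step_size: *", "", step)) else NA_real_
  vals <- readBin(raw[(offset + 1):length(raw)], "numeric",
                  n = (length(raw) - offset) / 4, size = 4,
                  endian = "little")
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  if (nrow(m) == 0 || !all(is.infinite(m[nrow(m), ])))
    stop("truncated TCK file: missing Inf terminator", call. = FALSE)
  m <- m[-nrow(m), , drop = FALSE]
  breaks <- which(is.nan(m[, 1]))
  streamlines <- list()
  start <- 1
  for (b in breaks) {
    if (b > start)
      streamlines[[length(streamlines) + 1]] <- m[start:(b - 1), , drop = FALSE]
    start <- b + 1
  }
  if (start <= nrow(m))
    streamlines[[length(streamlines) + 1]] <- m[start:nrow(m), , drop = FALSE]
  structure(list(streamlines = streamlines,
                 seed_index = rep(NA_integer_, length(streamlines)),
                 seed_vertex = rep(NA_integer_, length(streamlines)),
                 reason = rep(NA_character_, length(streamlines)),
                 step_mm = step_mm, seed = NA_integer_, grid = NULL),
            class = "streamline_set")
}

#' Write / read a pipeline configuration as sectioned key-value text
#'
#' Flat human-diffable format: `[section]` headers and `key = value` lines;
#' vectors are comma-separated; logicals are `true`/`false`. Unknown
#' sections or keys are rejected on read, and a written configuration reads
#' back identically.
#'
#' @param config a [default_config()] list.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  lines <- character(0)
  # top-level scalars first: anything after a [section] header would be
  # parsed as belonging to that section
  for (sec in names(config)) {
    if (!is.list(config[[sec]]))
      lines <- c(lines, sprintf("%s = %s", sec, format_kv(config[[sec]])))
  }
  for (sec in names(config)) {
    v <- config[[sec]]
    if (!is.list(v)) next
    lines <- c(lines, sprintf("[%s]", sec))
    for (k in names(v)) lines <- c(lines, sprintf("%s = %s", k,
                                                  format_kv(v[[k]])))
  }
  writeLines(lines, path)
  invisible(path)
}

format_kv <- function(x) {
  if (is.logical(x)) return(paste(ifelse(x, "true", "false"), collapse = ", "))
  if (is.character(x)) return(paste(x, collapse = ", "))
  paste(format(x, digits = 15, trim = TRUE, scientific = FALSE),
        collapse = ", ")
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ref <- default_config()
  cfg <- ref
  sec <- NULL
  for (raw_line in readLines(path)) {
    line <- trimws(sub("#.*$", "", raw_line))
    if (line == "") next
    if (grepl("^\\[.*\\]$", line)) {
      sec <- sub("^\\[(.*)\\]$", "\\1", line)
      if (!sec %in% names(ref) || !is.list(ref[[sec]]))
        stop(sprintf("unknown config section [%s]", sec), call. = FALSE)
      next
    }
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop(sprintf("malformed config line: %s", raw_line),
                              call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    template <- if (is.null(sec)) ref[[key]] else ref[[sec]][[key]]
    if (is.null(sec)) {
      if (!key %in% names(ref)) stop(sprintf("unknown config key %s", key),
                                     call. = FALSE)
      cfg[[key]] <- parse_kv(val, template)
    } else {
      if (!key %in% names(ref[[sec]]))
        stop(sprintf("unknown config key %s$%s", sec, key), call. = FALSE)
      cfg[[sec]][[key]] <- parse_kv(val, template)
    }
  }
  cfg
}

parse_kv <- function(val, template) {
  parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  if (is.logical(template)) return(tolower(parts) %in% c("true", "1", "yes"))
  if (is.character(template)) return(parts)
  out <- suppressWarnings(as.numeric(parts))
  if (anyNA(out) && !all(toupper(parts) == "NA")) return(parts)
  out
}

#' Write / read an evaluation report as JSON
#'
#' @param report an `eval_report`.
#' @param path file path.
#' @return `read_report()` returns the `eval_report` (metrics and seed
#'   round-trip exactly at the serialised precision).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(seed = report$seed, metrics = report$metrics,
         config = report$config),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- x$config
  if (!is.null(cfg$noise) && is.null(cfg$noise$snr))
    cfg$noise$snr <- NA_real_
  structure(list(metrics = x$metrics, config = cfg, seed = x$seed),
            class = "eval_report")
}
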