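#' Write an SH coefficient field as NIfTI with a basis sidecar
#'
#' The 4D NIfTI stores one coefficient volume per 4th-dimension index; a
#' JSON sidecar (`<path>.json` next to the image) records the basis
#' convention `{"basis": "real-sym-lex", "l_max": ...}` so coefficient
#' volumes are only interchanged with an explicit basis tag.
#'
#' @param field an [sh_field()].
#' @param path output NIfTI path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_sh_nifti <- function(field, path) {
  arr <- array(field$coef, dim = c(field$grid_shape, field$basis$n_coef))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(field$voxel_size, 1)
  RNifti::writeNifti(img, path)
  side <- sidecar_path(path)
  jsonlite::write_json(list(basis = "real-sym-lex", l_max = field$l_max),
                       side, auto_unbox = TRUE)
  invisible(path)
}

#' Read an SH coefficient field written by [write_sh_nifti()]
#'
#' @param path NIfTI path; the JSON sidecar must exist and declare the
#'   `real-sym-lex` basis.
#' @return an [sh_field()].
#' @export
read_sh_nifti <- function(path) {
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    stop("missing basis sidecar ", side,
         ": SH volumes require basis metadata {basis, l_max}")
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!identical(meta$basis, "real-sym-lex")) {
    stop("unsupported SH basis tag: ", meta$basis)
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  vs <- RNifti::pixdim(img)[1:3]
  coef <- matrix(as.numeric(img), prod(d[1:3]), d[4L])
  sh_field(coef, as.integer(meta$l_max), d[1:3], voxel_size = vs)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Read / write FSL-style gradient tables
#'
#' `bvec` is a 3 x N whitespace table of gradient components, `bval` a
#' 1 x N table of b-values. Non-unit bvec columns are normalized with a
#' warning.
#'
#' @param bvec_path,bval_path text file paths.
#' @return list with `gradients` (N x 3, unit rows) and `bvals` (length N).
#' @export
read_bvec_bval <- function(bvec_path, bval_path) {
  bv <- unname(as.matrix(utils::read.table(bvec_path)))
  if (nrow(bv) != 3L) bv <- t(bv)
  stopifnot(nrow(bv) == 3L)
  g <- t(bv)
  bvals <- as.numeric(utils::read.table(bval_path))
  stopifnot(length(bvals) == nrow(g))
  nrm <- sqrt(rowSums(g^2))
  nz <- nrm > 0
  if (any(abs(nrm[nz] - 1) > 1e-6)) {
    warning("non-unit bvec columns normalized")
  }
  g[nz, ] <- g[nz, ] / nrm[nz]
  list(gradients = g, bvals = bvals)
}

#' @rdname read_bvec_bval
#' @param gradients N x 3 matrix; @param bvals length-N numeric.
#' @export
write_bvec_bval <- function(gradients, bvals, bvec_path, bval_path) {
  utils::write.table(t(gradients), bvec_path, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(t(bvals), bval_path, row.names = FALSE,
                     col.names = FALSE)
  invisible(NULL)
}

#' Write streamlines in TCK format
#'
#' MRtrix track format: a text header (`mrtrix tracks`, `datatype:
#' Float32LE`, `count`, optional `step_size`, `file: . <offset>`, `END`),
#' followed by little-endian float32 point triplets with NaN triplets
#' separating tracks and an Inf triplet terminating the stream.
#'
#' @param bundle a [fiber_bundle()] (possibly with zero fibers).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tck <- function(bundle, path) {
  n <- length(bundle$fibers)
  hdr_lines <- c("mrtrix tracks", "datatype: Float32LE",
                 sprintf("count: %d", n))
  if (!is.na(bundle$step)) {
    hdr_lines <- c(hdr_lines, sprintf("step_size: %g", bundle$step))
  }
  # two-pass offset: header length including the "file" line and END
  probe <- function(off) {
    paste0(paste(c(hdr_lines, sprintf("file: . %d", off), "END"),
                 collapse = "\n"), "\n")
  }
  off <- nchar(probe(1000L), type = "bytes")
  off <- nchar(probe(off), type = "bytes")
  hdr <- probe(off)
  stopifnot(nchar(hdr, type = "bytes") == off)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (f in bundle$fibers) {
    writeBin(as.numeric(t(f)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read streamlines from a TCK file
#'
#' @param path TCK file path.
#' @return a [fiber_bundle()] (fibers with fewer than 2 points are
#'   dropped); zero-track files give an empty bundle.
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!identical(first, "mrtrix tracks")) {
    stop("malformed TCK header at byte 0: missing magic line")
  }
  fields <- list()
  offset <- NA_integer_
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("malformed TCK header: no END before EOF")
    if (identical(ln, "END")) break
    kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1L]]
    if (length(kv) != 3L) {
      stop(sprintf("malformed TCK header near byte %d: '%s'",
                   seek(con, NA), ln))
    }
    fields[[kv[2L]]] <- kv[3L]
    if (kv[2L] == "file") {
      offset <- as.integer(sub("^\\.\\s+", "", kv[3L]))
    }
  }
  if (is.na(offset)) stop("malformed TCK header: no file offset")
  dt <- fields[["datatype"]]
  if (!identical(dt, "Float32LE")) stop("unsupported TCK datatype: ", dt)
  seek(con, offset)
  raw <- readBin(con, "numeric", n = file.size(path), size = 4L,
                 endian = "little")
  pts <- matrix(raw, ncol = 3L, byrow = TRUE)
  fibers <- list()
  cur <- NULL
  for (r in seq_len(nrow(pts))) {
    p <- pts[r, ]
    if (all(is.infinite(p))) break
    if (all(is.nan(p))) {
      if (!is.null(cur) && nrow(cur) >= 2L) {
        fibers[[length(fibers) + 1L]] <- cur
      }
      cur <- NULL
    } else {
      cur <- rbind(cur, p)
    }
  }
  step <- if (!is.null(fields[["step_size"]])) {
    as.numeric(fields[["step_size"]])
  } else NA_real_
  if (length(fibers) == 0L) {
    return(structure(list(fibers = list(), tangents = list(),
                          n_total = 0L, step = step),
                     class = "fiber_bundle"))
  }
  fiber_bundle(lapply(fibers, unname), step = step)
}

#' Write a diffusion-weighted volume as NIfTI + bvec/bval
#'
#' @param dw a [dw_signal()].
#' @param path NIfTI path; bvec/bval are written next to it.
#' @return the path, invisibly.
#' @export
write_dwi <- function(dw, path) {
  arr <- array(dw$values, dim = c(dw$grid_shape, nrow(dw$gradients)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(dw$voxel_size, 1)
  RNifti::writeNifti(img, path)
  base <- sub("\\.nii(\\.gz)?$", "", path)
  write_bvec_bval(dw$gradients, rep(dw$b_value, nrow(dw$gradients)),
                  paste0(base, ".bvec"), paste0(base, ".bval"))
  invisible(path)
}

#' Read a diffusion-weighted volume written by [write_dwi()]
#'
#' @param path NIfTI path with sibling `.bvec` / `.bval` files.
#' @return a [dw_signal()].
#' @export
read_dwi <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  base <- sub("\\.nii(\\.gz)?$", "", path)
  gb <- read_bvec_bval(paste0(base, ".bvec"), paste0(base, ".bval"))
  dw_signal(matrix(as.numeric(img), prod(d[1:3]), d[4L]),
            gb$gradients, gb$bvals[1L], d[1:3],
            voxel_size = RNifti::pixdim(img)[1:3])
}
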