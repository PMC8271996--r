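# Sequence-file and checkpoint input/output.
#
# Text sequence format (one file per sequence):
#   header lines starting with '#':  "poserefine sequence v1", "T=", "fps=",
#   "beta=" (10 numbers), and a column note; then T whitespace-delimited rows
#   of 96 numbers -- 24 joints x (qw qx qy qz), scalar-first, canonical sign,
#   joint-major.
# Binary container: magic "PSQB", int32 version/T, float64 fps, 10 float64
# beta, then T*96 float64 quaternion components in row-major frame order.

.SEQ_MAGIC <- "PSQB"

#' Write a pose sequence to a file
#'
#' @param seq A `pose_sequence`.
#' @param path Output path.
#' @param format `"text"` (default, human-readable) or `"binary"` (compact).
#' @return `path`, invisibly.
#' @export
write_pose_sequence <- function(seq, path, format = c("text", "binary")) {
  stopifnot(inherits(seq, "pose_sequence"))
  format <- match.arg(format)
  T_ <- n_frames(seq)
  flat <- matrix(aperm(seq$quats, c(3L, 2L, 1L)), nrow = 96L)  # (96, T)
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "# poserefine sequence v1",
      sprintf("# T=%d", T_),
      sprintf("# fps=%.17g", seq$fps),
      paste("# beta=", paste(sprintf("%.17g", seq$beta), collapse = " ")),
      "# columns: 24 joints x (qw qx qy qz), scalar-first, canonical sign"
    ), con)
    utils::write.table(t(flat), con, row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(.SEQ_MAGIC, con, nchars = 4L, eos = NULL)
    writeBin(c(1L, T_), con, size = 4L)
    writeBin(as.numeric(c(seq$fps, seq$beta)), con, size = 8L)
    writeBin(as.numeric(flat), con, size = 8L)
  }
  invisible(path)
}

#' Read a pose sequence written by [write_pose_sequence()]
#'
#' The container (text or binary) is detected from the file's magic bytes.
#'
#' @param path Input path.
#' @return A `pose_sequence`.
#' @export
read_pose_sequence <- function(path) {
  magic <- readBin(path, "raw", n = 4L)
  if (identical(rawToChar(magic), .SEQ_MAGIC)) {
    con <- file(path, "rb")
    on.exit(close(con))
    readChar(con, 4L, useBytes = TRUE)
    hdr <- readBin(con, "integer", n = 2L, size = 4L)
    if (hdr[1L] != 1L) stop("unsupported sequence file version", call. = FALSE)
    T_ <- hdr[2L]
    nums <- readBin(con, "numeric", n = 11L, size = 8L)
    flat <- matrix(readBin(con, "numeric", n = 96L * T_, size = 8L), nrow = 96L)
    return(.seq_from_internal(array(flat, c(4L, 24L, T_)),
                              beta = nums[2:11], fps = nums[1L]))
  }
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_field <- function(key) {
    ln <- hdr[grepl(paste0(key, "="), hdr, fixed = TRUE)][1L]
    sub(paste0(".*", key, "=\\s*"), "", ln)
  }
  fps <- as.numeric(get_field("fps"))
  beta <- scan(text = get_field("beta"), quiet = TRUE)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  flat <- t(matrix(scan(text = paste(body, collapse = "\n"), quiet = TRUE),
                   ncol = 96L, byrow = TRUE))
  .seq_from_internal(array(flat, c(4L, 24L, ncol(flat))), beta = beta, fps = fps)
}

#' Save a trained refiner checkpoint
#'
#' Stores a flat container: format tag, the configuration used, the named
#' weight arrays (with their shapes) and the loss trace.  Round-tripping a
#' checkpoint reproduces evaluation results bit-identically.
#'
#' @param fit A `refiner_fit` (or bare `refiner_params`).
#' @param path Output path (RDS).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  params <- .as_params(fit)
  obj <- list(
    format = "poserefine-checkpoint-v1",
    variant = params$variant,
    n_window = params$n_window,
    hidden = params$hidden,
    weights = .params_flatten(params),
    shapes = lapply(.params_flatten(params), function(x) dim(x) %||% length(x)),
    config = if (inherits(fit, "refiner_fit")) fit$config,
    loss_trace = if (inherits(fit, "refiner_fit")) fit$loss_trace
  )
  saveRDS(obj, path)
  invisible(path)
}

#' Load a refiner checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return A `refiner_fit` (with `config`/`loss_trace` when present).
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "poserefine-checkpoint-v1")) {
    stop("not a poserefine checkpoint", call. = FALSE)
  }
  params <- refiner_params(obj$variant, obj$n_window, obj$hidden, seed = 1L)
  params <- .params_unflatten(params, obj$weights)
  structure(list(params = params, config = obj$config,
                 loss_trace = obj$loss_trace),
            class = "refiner_fit")
}
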