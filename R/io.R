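# .kss binary layout (little-endian):
#   header, 16 bytes: magic "KSS1" | u16 version=1 | u16 reserved=0 |
#                     u32 frame count | u32 nominal rate in mHz
#   frame, 508 bytes: f64 timestamp (s) |
#                     20 x (3 x f32 position + 1 validity byte) |
#                     20 x 3 x f32 orientation (deg)
# The validity byte packs the tracking state in its low 2 bits and the fusion
# provenance code in bits 2-4. Fixed-size frames make truncation detectable
# and allow seeking.

KSS_MAGIC <- charToRaw("KSS1")
KSS_VERSION <- 1L
KSS_FRAME_BYTES <- 508L
KSS_HEADER_BYTES <- 16L

f32_bytes <- function(values) {
  writeBin(as.numeric(values), raw(), size = 4, endian = "little")
}

#' Write a skeleton stream to a `.kss` binary file
#'
#' Positions are stored in single precision (sub-0.1 mm resolution at room
#' scale), timestamps in double precision. Output is byte-identical for
#' identical input. Recording metadata and exclusion intervals, which are not
#' part of the fixed-size binary frames, go to a JSON sidecar
#' (`<path>.json`) unless `sidecar = FALSE`.
#'
#' @param stream A [skeleton_stream()].
#' @param path Destination file path.
#' @param sidecar Write the metadata sidecar next to the binary?
#' @return `path`, invisibly.
#' @export
write_kss <- function(stream, path, sidecar = TRUE) {
  validate_skeleton_stream(stream)
  n <- n_frames(stream)
  rate <- attr(stream, "rate")

  header <- c(
    KSS_MAGIC,
    writeBin(KSS_VERSION, raw(), size = 2, endian = "little"),
    writeBin(0L, raw(), size = 2, endian = "little"),
    writeBin(n, raw(), size = 4, endian = "little"),
    writeBin(as.integer(round(rate * 1000)), raw(), size = 4, endian = "little")
  )

  body <- raw(0)
  if (n > 0) {
    xm <- matrix(stream$x, nrow = 20); ym <- matrix(stream$y, nrow = 20)
    zm <- matrix(stream$z, nrow = 20)
    oxm <- matrix(stream$ox, nrow = 20); oym <- matrix(stream$oy, nrow = 20)
    ozm <- matrix(stream$oz, nrow = 20)
    vbyte <- as.raw(state_code(stream$state) +
                      bitwShiftL(provenance_code(stream$provenance), 2))
    vm <- matrix(vbyte, nrow = 20)

    frame_mat <- matrix(as.raw(0), nrow = KSS_FRAME_BYTES, ncol = n)
    frame_mat[1:8, ] <- matrix(
      writeBin(frame_times(stream), raw(), size = 8, endian = "little"),
      nrow = 8
    )
    for (j in 1:20) {
      off <- 8L + (j - 1L) * 13L
      pos <- rbind(xm[j, ], ym[j, ], zm[j, ])  # x,y,z interleaved per frame
      frame_mat[off + 1:12, ] <- matrix(f32_bytes(as.vector(pos)), nrow = 12)
      frame_mat[off + 13L, ] <- vm[j, ]
      ooff <- 268L + (j - 1L) * 12L
      ori <- rbind(oxm[j, ], oym[j, ], ozm[j, ])
      frame_mat[ooff + 1:12, ] <- matrix(f32_bytes(as.vector(ori)), nrow = 12)
    }
    body <- as.vector(frame_mat)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, body), con)

  if (sidecar) {
    meta <- list(
      participant = attr(stream, "participant"),
      condition = attr(stream, "condition"),
      camera = attr(stream, "camera"),
      exclusions = as.data.frame(attr(stream, "exclusions"))
    )
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         null = "null", na = "null", digits = NA)
  }
  invisible(path)
}

#' Read a skeleton stream from a `.kss` binary file
#'
#' Rejects files with an unknown magic number or version and reports the
#' index of the offending frame for truncated files. If a metadata sidecar
#' (`<path>.json`) is present it is read back as well and any exclusion
#' intervals re-flagged.
#'
#' @param path `.kss` file written by [write_kss()].
#' @return A [skeleton_stream()].
#' @export
read_kss <- function(path) {
  if (!file.exists(path)) {
    abort_validation(paste0("stream file not found: ", path))
  }
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  if (size < KSS_HEADER_BYTES) abort_format("not a .kss file: shorter than header")
  magic <- readBin(con, "raw", 4)
  if (!identical(magic, KSS_MAGIC)) {
    abort_format(sprintf("not a .kss file: bad magic 0x%s",
                         paste(sprintf("%02x", as.integer(magic)), collapse = "")))
  }
  version <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "integer", 1, size = 2, endian = "little")  # reserved
  if (version != KSS_VERSION) {
    abort_format(sprintf("unsupported .kss version %d", version))
  }
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  rate <- readBin(con, "integer", 1, size = 4, endian = "little") / 1000

  body_bytes <- size - KSS_HEADER_BYTES
  if (body_bytes != n * KSS_FRAME_BYTES) {
    abort_format(sprintf(
      "corrupt .kss file: %d frames declared but file truncated in frame %d",
      n, floor(body_bytes / KSS_FRAME_BYTES) + 1
    ))
  }

  if (n == 0) {
    time <- numeric(0)
    mk <- function() matrix(numeric(0), 0, 20)
    stream <- stream_from_matrices(time, mk(), mk(), mk(),
                                   matrix(character(0), 0, 20), rate = rate)
  } else {
    frame_mat <- matrix(readBin(con, "raw", n * KSS_FRAME_BYTES),
                        nrow = KSS_FRAME_BYTES)
    time <- readBin(as.vector(frame_mat[1:8, ]), "double", n,
                    size = 8, endian = "little")
    xm <- ym <- zm <- oxm <- oym <- ozm <- matrix(0, n, 20)
    state_m <- matrix("", n, 20)
    prov_m <- matrix(NA_character_, n, 20)
    any_prov <- FALSE
    for (j in 1:20) {
      off <- 8L + (j - 1L) * 13L
      pos <- matrix(readBin(as.vector(frame_mat[off + 1:12, ]), "double",
                            3 * n, size = 4, endian = "little"), nrow = 3)
      xm[, j] <- pos[1, ]; ym[, j] <- pos[2, ]; zm[, j] <- pos[3, ]
      vb <- as.integer(frame_mat[off + 13L, ])
      state_m[, j] <- tracking_states()[bitwAnd(vb, 3L) + 1L]
      pcode <- bitwShiftR(vb, 2)
      if (any(pcode > 0)) {
        any_prov <- TRUE
        prov_m[pcode > 0, j] <- fusion_provenance()[pcode[pcode > 0]]
      }
      ooff <- 268L + (j - 1L) * 12L
      ori <- matrix(readBin(as.vector(frame_mat[ooff + 1:12, ]), "double",
                            3 * n, size = 4, endian = "little"), nrow = 3)
      oxm[, j] <- ori[1, ]; oym[, j] <- ori[2, ]; ozm[, j] <- ori[3, ]
    }
    stream <- stream_from_matrices(
      time, xm, ym, zm, state_m, oxm, oym, ozm, rate = rate,
      provenance = if (any_prov) prov_m else NULL
    )
  }

  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(stream, "participant") <- meta$participant %||% NA_character_
    attr(stream, "condition") <- meta$condition %||% NA_character_
    attr(stream, "camera") <- meta$camera %||% NA_character_
    excl <- meta$exclusions
    if (!is.null(excl) && NROW(excl) > 0) {
      stream <- apply_exclusions(stream, as.data.frame(excl))
    }
  }
  stream
}

#' JSONL interchange for skeleton streams
#'
#' One frame per line: timestamp, per-joint position/state (and provenance if
#' fused), per-joint orientation. Intended for debugging and plain-text
#' fixtures, not bulk storage.
#'
#' @param stream A [skeleton_stream()].
#' @param path Destination (`write_stream_jsonl`) or source
#'   (`read_stream_jsonl`) file.
#' @return `path` invisibly, or the stream.
#' @export
write_stream_jsonl <- function(stream, path) {
  validate_skeleton_stream(stream)
  n <- n_frames(stream)
  lines <- character(n)
  for (i in seq_len(n)) {
    fr <- stream[((i - 1) * 20 + 1):(i * 20), ]
    joints <- lapply(seq_len(20), function(j) {
      rec <- list(p = c(fr$x[j], fr$y[j], fr$z[j]), state = fr$state[j])
      if (!is.na(fr$provenance[j])) rec$prov <- fr$provenance[j]
      rec
    })
    names(joints) <- fr$joint
    orient <- lapply(seq_len(20), function(j) c(fr$ox[j], fr$oy[j], fr$oz[j]))
    names(orient) <- fr$joint
    lines[i] <- jsonlite::toJSON(
      list(time = fr$time[1], joints = joints, orient = orient),
      auto_unbox = TRUE, digits = NA
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_stream_jsonl
#' @param rate Nominal frame rate of the reconstructed stream.
#' @export
read_stream_jsonl <- function(path, rate = 30) {
  lines <- readLines(path)
  n <- length(lines)
  time <- numeric(n)
  xm <- ym <- zm <- oxm <- oym <- ozm <- matrix(0, n, 20)
  state_m <- matrix("", n, 20)
  prov_m <- matrix(NA_character_, n, 20)
  any_prov <- FALSE
  for (i in seq_len(n)) {
    rec <- jsonlite::fromJSON(lines[i], simplifyVector = TRUE)
    time[i] <- rec$time
    for (j in seq_len(20)) {
      nm <- skeleton_joints()[j]
      xm[i, j] <- rec$joints[[nm]]$p[1]
      ym[i, j] <- rec$joints[[nm]]$p[2]
      zm[i, j] <- rec$joints[[nm]]$p[3]
      state_m[i, j] <- rec$joints[[nm]]$state
      if (!is.null(rec$joints[[nm]]$prov)) {
        prov_m[i, j] <- rec$joints[[nm]]$prov
        any_prov <- TRUE
      }
      oxm[i, j] <- rec$orient[[nm]][1]
      oym[i, j] <- rec$orient[[nm]][2]
      ozm[i, j] <- rec$orient[[nm]][3]
    }
  }
  stream_from_matrices(time, xm, ym, zm, state_m, oxm, oym, ozm, rate = rate,
                       provenance = if (any_prov) prov_m else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
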