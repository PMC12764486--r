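## Video clips, AVI I/O, temporal sampling, resizing, augmentation, manifests.

#' Construct a video clip
#'
#' A `video_clip` is the package's in-memory unit of video data: a rank-4
#' pixel array `T x C x H x W` with values in `[0, 1]`, together with the
#' indices of the raw-video frames each sampled frame came from (0-based, so
#' downstream sparse positional encodings can use them directly) and a source
#' identifier.
#'
#' @param pixels numeric array with `dim = c(T, C, H, W)`, `C = 3`, values in
#'   `[0, 1]`.
#' @param frame_indices integer vector of length `T`; 0-based indices into the
#'   raw source video, non-decreasing.
#' @param source_id character scalar naming the source (path or label).
#' @return an object of class `video_clip`.
#' @export
video_clip <- function(pixels, frame_indices = seq_len(dim(pixels)[1]) - 1L,
                       source_id = "<memory>") {
  assert_that(is.array(pixels) && length(dim(pixels)) == 4L,
              "pixels must be a rank-4 array T x C x H x W")
  d <- dim(pixels)
  assert_that(d[1] >= 1L, "clip must contain at least one frame")
  assert_that(d[2] == 3L, "clip must have 3 channels")
  assert_that(all(is.finite(pixels)), "clip pixels must be finite")
  assert_that(min(pixels) >= 0 && max(pixels) <= 1,
              "clip pixels must lie in [0, 1]")
  frame_indices <- as.integer(frame_indices)
  assert_that(length(frame_indices) == d[1],
              "frame_indices must have one entry per frame")
  assert_that(all(diff(frame_indices) >= 0L),
              "frame_indices must be non-decreasing")
  structure(list(pixels = pixels, frame_indices = frame_indices,
                 source_id = as.character(source_id)),
            class = "video_clip")
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<video_clip> %d frames, %d x %d x %d, source: %s\n",
              d[1], d[2], d[3], d[4], x$source_id))
  invisible(x)
}

#' @export
dim.video_clip <- function(x) dim(x$pixels)

## ---------------------------------------------------------------------------
## Uncompressed AVI (RIFF, raw DIB frames)
##
## This environment has no ffmpeg; the package reads and writes the
## uncompressed subset of AVI: RGB24 (or 8-bit grayscale) bottom-up DIB
## frames in '00db'/'00dc' chunks. Files written here are valid AVI playable
## by any standard decoder.

.fourcc <- function(con) rawToChar(readBin(con, "raw", 4L))
.u32 <- function(con) readBin(con, "integer", 1L, size = 4L, endian = "little")
.w_fourcc <- function(con, s) writeBin(charToRaw(s), con)
.w_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4L, endian = "little")
.w_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2L, endian = "little")

#' Read a video file into a raw frame stack
#'
#' Decodes an uncompressed AVI into a `T_raw x 3 x H x W` array with values
#' scaled to `[0, 1]`. Grayscale (8-bit) sources are replicated to three
#' identical channels. Only raw-DIB AVI is supported (no codecs are available
#' in this environment); files produced by [write_video()] round-trip exactly.
#'
#' @param path path to an AVI file.
#' @return numeric array `T_raw x 3 x H x W` in `[0, 1]`.
#' @export
read_video <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "raw", 4L)
  if (length(magic) < 4L || rawToChar(magic) != "RIFF") {
    stop2(sprintf("decode error: '%s' is not a RIFF/AVI file", path))
  }
  .u32(con)                               # riff size
  if (.fourcc(con) != "AVI ") stop2("decode error: RIFF file is not AVI")

  width <- NULL; height <- NULL; bitcount <- NULL; compression <- NULL
  frames <- list()

  parse_chunks <- function(end_pos) {
    while (seek(con, where = NA) < end_pos) {
      id <- .fourcc(con)
      if (nchar(id) < 4L) break
      sz <- .u32(con)
      start <- seek(con, where = NA)
      if (id == "LIST") {
        .fourcc(con)                      # list type; descend regardless
        parse_chunks(start + sz)
      } else if (id == "strf") {
        .u32(con)                         # biSize
        width <<- .u32(con)
        height <<- .u32(con)
        .w <- readBin(con, "integer", 1L, size = 2L, endian = "little") # planes
        bitcount <<- readBin(con, "integer", 1L, size = 2L, endian = "little")
        compression <<- .u32(con)
      } else if (grepl("^..d[bc]$", id)) {
        frames[[length(frames) + 1L]] <<- readBin(con, "raw", sz)
      }
      seek(con, where = start + sz + (sz %% 2L))  # chunks are word-aligned
    }
  }
  seek(con, where = 0L, origin = "end"); file_end <- seek(con, where = NA)
  seek(con, where = 12L)
  parse_chunks(file_end)

  if (is.null(width)) stop2("decode error: no stream format (strf) found")
  if (!is.null(compression) && compression != 0L) {
    stop2("decode error: only uncompressed (raw DIB) AVI is supported")
  }
  if (length(frames) == 0L) stop2("empty-video error: AVI contains no frames")
  bypp <- bitcount %/% 8L
  assert_that(bypp %in% c(1L, 3L), "decode error: unsupported bit depth")
  row_bytes <- ((width * bypp + 3L) %/% 4L) * 4L

  out <- array(0, dim = c(length(frames), 3L, height, width))
  for (f in seq_along(frames)) {
    buf <- frames[[f]]
    assert_that(length(buf) >= row_bytes * height, "decode error: short frame")
    m <- matrix(as.integer(buf[seq_len(row_bytes * height)]),
                nrow = row_bytes, ncol = height)       # column = one DIB row
    m <- m[seq_len(width * bypp), height:1, drop = FALSE] # strip pad, flip
    if (bypp == 1L) {
      fr <- t(m) / 255                                  # H x W intensities
      for (c in 1:3) out[f, c, , ] <- fr
    } else {
      # rows are B,G,R triples left to right
      for (c in 1:3) out[f, c, , ] <- t(m[seq(4L - c, width * 3L, by = 3L), ,
                                          drop = FALSE]) / 255
    }
  }
  out
}

#' Write a frame stack or clip as uncompressed AVI
#'
#' @param frames a `video_clip`, or a numeric array `T x C x H x W` with
#'   `C` 1 or 3 and values in `[0, 1]`.
#' @param path output path.
#' @param fps frames per second stamped in the header.
#' @return `path`, invisibly.
#' @export
write_video <- function(frames, path, fps = 30) {
  if (inherits(frames, "video_clip")) frames <- frames$pixels
  d <- dim(frames)
  assert_that(length(d) == 4L && d[2] %in% c(1L, 3L),
              "frames must be T x C x H x W with C in {1, 3}")
  assert_that(all(is.finite(frames)) && min(frames) >= 0 && max(frames) <= 1,
              "pixel values must be finite and in [0, 1]")
  Tn <- d[1]; Cn <- d[2]; H <- d[3]; W <- d[4]
  bypp <- if (Cn == 1L) 1L else 3L
  row_bytes <- ((W * bypp + 3L) %/% 4L) * 4L
  frame_bytes <- row_bytes * H
  palette_bytes <- if (bypp == 1L) 256L * 4L else 0L
  strf_sz <- 40L + palette_bytes

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)

  hdrl_sz <- 4L + 8L + 56L + (8L + 4L + 8L + 56L + 8L + strf_sz)
  movi_sz <- 4L + Tn * (8L + frame_bytes)
  riff_sz <- 4L + (8L + hdrl_sz) + (8L + movi_sz)

  .w_fourcc(con, "RIFF"); .w_u32(con, riff_sz); .w_fourcc(con, "AVI ")
  .w_fourcc(con, "LIST"); .w_u32(con, hdrl_sz); .w_fourcc(con, "hdrl")
  .w_fourcc(con, "avih"); .w_u32(con, 56L)
  .w_u32(con, round(1e6 / fps)); .w_u32(con, frame_bytes * fps)
  .w_u32(con, 0L); .w_u32(con, 0L); .w_u32(con, Tn); .w_u32(con, 0L)
  .w_u32(con, 1L); .w_u32(con, frame_bytes); .w_u32(con, W); .w_u32(con, H)
  for (i in 1:4) .w_u32(con, 0L)
  strl_sz <- 4L + 8L + 56L + 8L + strf_sz
  .w_fourcc(con, "LIST"); .w_u32(con, strl_sz); .w_fourcc(con, "strl")
  .w_fourcc(con, "strh"); .w_u32(con, 56L)
  .w_fourcc(con, "vids"); .w_fourcc(con, "DIB ")
  .w_u32(con, 0L); .w_u16(con, 0L); .w_u16(con, 0L); .w_u32(con, 0L)
  .w_u32(con, 1L); .w_u32(con, round(fps))       # scale, rate
  .w_u32(con, 0L); .w_u32(con, Tn); .w_u32(con, frame_bytes)
  .w_u32(con, -1L); .w_u32(con, 0L)
  .w_u16(con, 0L); .w_u16(con, 0L); .w_u16(con, W); .w_u16(con, H)
  .w_fourcc(con, "strf"); .w_u32(con, strf_sz)
  .w_u32(con, 40L); .w_u32(con, W); .w_u32(con, H)
  .w_u16(con, 1L); .w_u16(con, bypp * 8L)
  .w_u32(con, 0L); .w_u32(con, frame_bytes)
  .w_u32(con, 0L); .w_u32(con, 0L)
  .w_u32(con, if (bypp == 1L) 256L else 0L); .w_u32(con, 0L)
  if (bypp == 1L) {
    pal <- as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256L)))
    writeBin(pal, con)
  }
  .w_fourcc(con, "LIST"); .w_u32(con, movi_sz); .w_fourcc(con, "movi")

  for (f in seq_len(Tn)) {
    .w_fourcc(con, "00db"); .w_u32(con, frame_bytes)
    m <- matrix(raw(1L), nrow = row_bytes, ncol = H)
    if (bypp == 1L) {
      px <- round(frames[f, 1, , ] * 255)             # H x W
      m[seq_len(W), ] <- as.raw(t(px[H:1, , drop = FALSE]))
    } else {
      bgr <- array(0L, dim = c(3L, W, H))
      for (c in 1:3) {
        bgr[4L - c, , ] <- round(t(frames[f, c, H:1, , drop = FALSE][1, 1, , ]) * 255)
      }
      m[seq_len(W * 3L), ] <- as.raw(bgr)
    }
    writeBin(as.vector(m), con)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Sampling, resizing, augmentation

#' Uniformly sample T frames from a raw frame stack
#'
#' Uses the deterministic rule `index_k = floor(k * T_raw / T)` for
#' `k = 0..T-1`. When the source is shorter than `T` the indices repeat
#' (padding by frame repetition); when `T_raw >= T` they are strictly
#' increasing.
#'
#' @param frames raw frame stack `T_raw x C x H x W` (from [read_video()]).
#' @param T number of frames to sample.
#' @param source_id source label recorded on the clip.
#' @return a [video_clip()] with `source_frame_indices` filled in.
#' @export
uniform_temporal_sample <- function(frames, T, source_id = "<memory>") {
  assert_that(is_count(T), "T must be a positive integer")
  d <- dim(frames)
  assert_that(length(d) == 4L, "frames must be a rank-4 array")
  T_raw <- d[1]
  if (T_raw == 0L) stop2("empty-video error: raw stack has no frames")
  idx0 <- floor((0:(T - 1)) * T_raw / T)          # 0-based
  video_clip(frames[idx0 + 1L, , , , drop = FALSE],
             frame_indices = idx0, source_id = source_id)
}

# Bilinear interpolation weight matrix mapping n_in samples to n_out, using
# the half-pixel-center convention with edge clamping. Rows sum to 1.
bilinear_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * scale - 0.5     # 0-based source coords
  lo <- floor(src)
  fr <- src - lo
  lo_c <- pmin(pmax(lo, 0), n_in - 1)
  hi_c <- pmin(pmax(lo + 1, 0), n_in - 1)
  for (i in seq_len(n_out)) {
    W[i, lo_c[i] + 1L] <- W[i, lo_c[i] + 1L] + (1 - fr[i])
    W[i, hi_c[i] + 1L] <- W[i, hi_c[i] + 1L] + fr[i]
  }
  W
}

#' Resize a clip with bilinear interpolation and clamp to [0, 1]
#'
#' @param clip a [video_clip()].
#' @param H,W target spatial size.
#' @return a resized [video_clip()].
#' @export
resize_and_normalize <- function(clip, H, W) {
  assert_that(inherits(clip, "video_clip"), "clip must be a video_clip")
  assert_that(is_count(H) && is_count(W), "H and W must be positive integers")
  assert_that(all(is.finite(clip$pixels)), "data error: non-finite pixels")
  d <- dim(clip$pixels)
  Wh <- bilinear_weights(d[3], H)
  Ww <- bilinear_weights(d[4], W)
  out <- array(0, dim = c(d[1], d[2], H, W))
  for (f in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      out[f, c, , ] <- Wh %*% clip$pixels[f, c, , ] %*% t(Ww)
    }
  }
  video_clip(clip01(out), frame_indices = clip$frame_indices,
             source_id = clip$source_id)
}

#' Randomly mirror a clip on the width axis
#'
#' With probability `p` (decided once per clip, reproducibly under `seed`)
#' every frame is flipped left-right; labels attached elsewhere are
#' unaffected. The flip is consistent across frames.
#'
#' @param clip a [video_clip()].
#' @param p flip probability in `[0, 1]`.
#' @param seed integer seed for the flip decision.
#' @return a [video_clip()].
#' @export
random_horizontal_flip <- function(clip, p = 0.5, seed = NULL) {
  assert_that(is.numeric(p) && p >= 0 && p <= 1, "p must be in [0, 1]")
  flip <- with_seed(seed, stats::runif(1) < p)
  if (!flip) return(clip)
  d <- dim(clip$pixels)
  video_clip(clip$pixels[, , , d[4]:1, drop = FALSE],
             frame_indices = clip$frame_indices, source_id = clip$source_id)
}

## ---------------------------------------------------------------------------
## Label manifests

.valid_splits <- c("train", "val", "test")

#' Read a dataset manifest
#'
#' Manifests are long-format CSV with header `path,split,label_name,label_value`;
#' one row per (clip, label). Split tags must be `train`/`val`/`test`,
#' consistent per clip, and a label name may appear at most once per clip.
#'
#' @param path CSV path.
#' @return a `data.frame` with the four manifest columns.
#' @export
read_manifest <- function(path) {
  assert_that(file.exists(path), sprintf("manifest not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(df)
}

#' Validate (and return) a manifest data frame
#' @param df data.frame with columns path, split, label_name, label_value.
#' @return `df`, invisibly checked.
#' @export
validate_manifest <- function(df) {
  need <- c("path", "split", "label_name", "label_value")
  assert_that(all(need %in% names(df)),
              sprintf("manifest must have columns: %s", paste(need, collapse = ", ")))
  assert_that(all(df$split %in% .valid_splits),
              "manifest split tags must be train/val/test")
  key <- paste(df$path, df$label_name, sep = "\r")
  assert_that(!anyDuplicated(key),
              "duplicate (path, label_name) pair in manifest")
  sp <- tapply(df$split, df$path, function(s) length(unique(s)))
  assert_that(all(sp == 1L), "a clip path maps to more than one split")
  df
}

#' Write a manifest CSV
#' @param df manifest data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(df, path) {
  validate_manifest(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Pivot a manifest to one row per clip with label columns; internal.
manifest_wide <- function(df, label) {
  sub <- df[df$label_name == label, , drop = FALSE]
  sub[order(sub$path), c("path", "split", "label_value")]
}
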