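## Synthetic echocardiogram phantom: a beating elliptical chamber inside a
## speckled ultrasound sector, with analytically known EF / ESV / EDV.

#' Phantom generation parameters
#'
#' Describes one synthetic echo clip: a dark elliptical blood pool
#' ("chamber") embedded in brighter tissue, inside an ultrasound scan
#' sector, with multiplicative speckle. The chamber's semi-axes contract
#' smoothly (raised cosine) from end-diastole (ED) to end-systole (ES)
#' within each cardiac cycle; volumes use the single-plane
#' prolate-ellipsoid proxy `Vol = vol_scale * a * b^2`, so
#' `EF = 100 * (1 - (1 - contraction)^3)` exactly.
#'
#' @param T_raw frames per raw video.
#' @param H,W frame size in pixels.
#' @param cycle_length frames per cardiac cycle (>= 2).
#' @param a_ED,b_ED end-diastolic semi-axes in pixels (long, short).
#' @param contraction fractional reduction of both semi-axes at ES, in (0,1).
#' @param speckle_sigma multiplicative log-normal speckle scale (>= 0).
#' @param sector_angle full opening angle of the scan sector, degrees.
#' @param vol_scale converts pixel^3 of `a*b^2` to ml-equivalent units.
#' @param seed integer seed controlling the speckle field.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(T_raw = 24L, H = 32L, W = 32L, cycle_length = 12L,
                           a_ED = 9, b_ED = 6, contraction = 0.2,
                           speckle_sigma = 0.15, sector_angle = 75,
                           vol_scale = 0.5, seed = 1L) {
  assert_that(is_count(T_raw) && is_count(H) && is_count(W),
              "T_raw, H, W must be positive integers")
  assert_that(is_count(cycle_length) && cycle_length >= 2,
              "parameter error: cycle_length must be >= 2")
  assert_that(a_ED > 0 && b_ED > 0, "parameter error: semi-axes must be > 0")
  assert_that(contraction > 0 && contraction < 1,
              "parameter error: contraction must lie in (0, 1)")
  assert_that(speckle_sigma >= 0, "parameter error: speckle_sigma must be >= 0")
  assert_that(sector_angle > 0 && sector_angle <= 180,
              "parameter error: sector_angle must be in (0, 180]")
  structure(list(T_raw = as.integer(T_raw), H = as.integer(H), W = as.integer(W),
                 cycle_length = as.integer(cycle_length), a_ED = a_ED,
                 b_ED = b_ED, contraction = contraction,
                 speckle_sigma = speckle_sigma, sector_angle = sector_angle,
                 vol_scale = vol_scale, seed = as.integer(seed)),
            class = "phantom_params")
}

#' Ejection fraction implied by a fractional contraction
#'
#' Under the prolate-ellipsoid proxy `Vol = const * a * b^2` with both
#' semi-axes scaled by `(1 - contraction)` at end-systole,
#' `EF = 100 * (1 - (1 - contraction)^3)` percent.
#'
#' @param contraction fractional semi-axis reduction in (0, 1).
#' @return EF in percent.
#' @export
ef_from_contraction <- function(contraction) {
  100 * (1 - (1 - contraction)^3)
}

#' Generate one labeled phantom clip
#'
#' @param params a [phantom_params()] object.
#' @return a list of class `labeled_clip` with fields `clip` (a
#'   [video_clip()]), `ef` (%), `esv`, `edv` (ml-equivalent).
#' @export
generate_phantom <- function(params) {
  assert_that(inherits(params, "phantom_params"),
              "params must come from phantom_params()")
  p <- params
  # raised-cosine systolic phase: 0 at ED (frame 0 of each cycle), 1 at ES
  phase <- 2 * pi * (seq_len(p$T_raw) - 1) / p$cycle_length
  sys_frac <- (1 - cos(phase)) / 2
  scale_t <- 1 - p$contraction * sys_frac

  # sector mask: apex at top-center, opening downwards
  cy <- 1.5                                # apex slightly above the frame
  cx <- (p$W + 1) / 2
  half <- p$sector_angle / 2 * pi / 180
  rows <- matrix(seq_len(p$H), p$H, p$W)
  cols <- matrix(seq_len(p$W), p$H, p$W, byrow = TRUE)
  ang <- atan2(cols - cx, rows - cy)       # 0 = straight down
  sector <- abs(ang) <= half

  # chamber center: midway down the sector
  ec_y <- p$H * 0.55
  ec_x <- cx

  base <- array(0, dim = c(p$T_raw, 3L, p$H, p$W))
  tissue <- 0.55
  blood <- 0.08
  for (f in seq_len(p$T_raw)) {
    a <- p$a_ED * scale_t[f]               # vertical (long-axis) semi-axis
    b <- p$b_ED * scale_t[f]
    inside <- ((rows - ec_y) / a)^2 + ((cols - ec_x) / b)^2 <= 1
    fr <- matrix(tissue, p$H, p$W)
    fr[inside] <- blood
    fr[!sector] <- 0
    for (c in 1:3) base[f, c, , ] <- fr
  }

  if (p$speckle_sigma > 0) {
    noise <- with_seed(p$seed, {
      array(exp(p$speckle_sigma * stats::rnorm(p$T_raw * p$H * p$W)),
            dim = c(p$T_raw, p$H, p$W))
    })
    for (c in 1:3) base[, c, , ] <- base[, c, , ] * noise
  }
  base <- clip01(base)

  edv <- p$vol_scale * p$a_ED * p$b_ED^2
  esv <- edv * (1 - p$contraction)^3
  ef <- 100 * (edv - esv) / edv
  clip <- video_clip(base, frame_indices = seq_len(p$T_raw) - 1L,
                     source_id = sprintf("phantom(seed=%d)", p$seed))
  structure(list(clip = clip, ef = ef, esv = esv, edv = edv),
            class = "labeled_clip")
}

#' @export
print.labeled_clip <- function(x, ...) {
  cat(sprintf("<labeled_clip> EF %.1f%%, ESV %.1f, EDV %.1f; ", x$ef, x$esv, x$edv))
  print(x$clip)
  invisible(x)
}

#' Generate a labeled phantom dataset on disk
#'
#' Draws `contraction` uniformly from `contraction_range` for each clip
#' (hence a known EF distribution), writes one uncompressed AVI per clip,
#' and a long-format manifest CSV with `ef`, `esv`, `edv` labels. Splits are
#' assigned deterministically: the first `floor(f_train * n)` clips (in a
#' seeded random order) are train, the next `floor(f_val * n)` are val, the
#' remainder test.
#'
#' @param n number of clips (>= 1).
#' @param out_dir output directory (created if missing).
#' @param contraction_range length-2 numeric range inside (0, 1).
#' @param split_fractions numeric `(train, val)` fractions; test is the rest.
#' @param base_params a [phantom_params()] giving all non-varied parameters.
#' @param seed integer master seed (per-clip seeds are derived from it).
#' @return the manifest data frame (also written to `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(n, out_dir,
                             contraction_range = c(0.05, 0.35),
                             split_fractions = c(0.7, 0.15),
                             base_params = phantom_params(),
                             seed = 1L) {
  assert_that(is_count(n), "n must be a positive integer")
  assert_that(length(contraction_range) == 2L &&
                all(contraction_range > 0) && all(contraction_range < 1) &&
                contraction_range[1] <= contraction_range[2],
              "contraction_range must lie inside (0, 1)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(out_dir), sprintf("cannot create directory: %s", out_dir))

  contr <- with_seed(derive_seed(seed, "contraction"),
                     stats::runif(n, contraction_range[1], contraction_range[2]))
  ord <- with_seed(derive_seed(seed, "split"), sample.int(n))
  n_train <- floor(split_fractions[1] * n)
  n_val <- floor(split_fractions[2] * n)
  split <- character(n)
  split[ord[seq_len(n_train)]] <- "train"
  split[ord[n_train + seq_len(n_val)]] <- "val"
  split[ord[-seq_len(n_train + n_val)]] <- "test"

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- base_params
    p$contraction <- contr[i]
    p$seed <- derive_seed(seed, paste0("clip", i))
    lab <- generate_phantom(p)
    clip_path <- file.path(out_dir, sprintf("clip_%04d.avi", i))
    write_video(lab$clip, clip_path)
    rows[[i]] <- data.frame(
      path = clip_path, split = split[i],
      label_name = c("ef", "esv", "edv"),
      label_value = c(lab$ef, lab$esv, lab$edv),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
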