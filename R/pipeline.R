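#' Denoising configuration
#'
#' Bundles every tunable of the wavelet denoising pipeline.  The three
#' classical method presets are `{universal + soft}` (VisuShrink),
#' `{bayes + soft}` (BayesShrink) and `{proposed + adaptive}` (the
#' reference-weighted method); arbitrary threshold/shrinkage
#' combinations are allowed for experimentation.
#'
#' @param wavelet Wavelet name (default `"bior3.9"`).
#' @param levels Decomposition depth (default 3).
#' @param threshold_method `"universal"`, `"bayes"` or `"proposed"`.
#' @param shrink_method `"hard"`, `"soft"`, `"semisoft"` or
#'   `"adaptive"`.
#' @param alpha Semi-soft weight in `[0, 1]` (default 0.5).
#' @param log_base `"natural"` or `"ten"` for the threshold logarithms.
#' @param eq13_parse Placement of `beta` in the proposed threshold:
#'   `"product"` (default) or `"divide_beta"`.
#' @param n_convention `"image"` (N = total pixels, default) or
#'   `"subband"` (N = coefficients in the subband being thresholded).
#' @param clip_output Clamp the reconstruction into the valid intensity
#'   range?  Off by default so metrics see the raw estimate.
#' @return A `denoise_config` list.
#' @export
denoise_config <- function(wavelet = "bior3.9", levels = 3L,
                           threshold_method = c("universal", "bayes", "proposed"),
                           shrink_method = c("soft", "hard", "semisoft", "adaptive"),
                           alpha = 0.5, log_base = "natural",
                           eq13_parse = "product",
                           n_convention = c("image", "subband"),
                           clip_output = FALSE) {
  cfg_error <- function(msg) {
    stop(errorCondition(msg, class = c("lpwave_config_error", "error", "condition")))
  }
  threshold_method <- match.arg(threshold_method)
  shrink_method <- match.arg(shrink_method)
  n_convention <- match.arg(n_convention)
  if (!is.numeric(levels) || length(levels) != 1L || levels < 1) {
    cfg_error("`levels` must be an integer >= 1")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    cfg_error("`alpha` must be in [0, 1]")
  }
  log_base <- match.arg(log_base, c("natural", "ten"))
  eq13_parse <- match.arg(eq13_parse, c("product", "divide_beta"))
  wavelet_filters(wavelet)  # fail early on unknown wavelet
  structure(
    list(wavelet = wavelet, levels = as.integer(levels),
         threshold_method = threshold_method, shrink_method = shrink_method,
         alpha = alpha, log_base = log_base, eq13_parse = eq13_parse,
         n_convention = n_convention, clip_output = isTRUE(clip_output)),
    class = "denoise_config"
  )
}

#' @export
print.denoise_config <- function(x, ...) {
  cat(sprintf("<denoise_config> %s, %d level(s), threshold = %s, shrink = %s\n",
              x$wavelet, x$levels, x$threshold_method, x$shrink_method))
  invisible(x)
}

needs_reference <- function(config) {
  config$threshold_method == "proposed" || config$shrink_method == "adaptive"
}

#' Denoise an image by wavelet shrinkage
#'
#' The full pipeline: decompose the noisy image, estimate the noise
#' standard deviation from the finest diagonal subband, compute the
#' configured threshold (globally, per level, or per subband), apply the
#' configured shrinkage rule to every detail subband, and reconstruct.
#' The approximation subband is never shrunk.
#'
#' The `proposed` threshold and the `adaptive` shrinkage rule both need
#' the linear prediction factor and therefore a clean (or earlier-frame)
#' reference image of the same size; the pipeline fails loudly when it
#' is missing rather than inventing a proxy.
#'
#' @param noisy Noisy input image (`image_grid` or matrix).
#' @param config A [denoise_config()].
#' @param reference Optional reference image, required for the proposed
#'   method.
#' @return The denoised `image_grid`.  Attribute `denoise_info` records
#'   the estimated sigma, the prediction factor (if any) and the
#'   thresholds actually applied.
#' @examples
#' clean <- brain_phantom(64, seed = 1)
#' noisy <- add_gaussian_noise(clean, 0.01, seed = 2)
#' cfg <- denoise_config(threshold_method = "proposed", shrink_method = "adaptive")
#' out <- denoise(noisy, cfg, reference = clean)
#' psnr(255 * as.matrix(clean), 255 * as.matrix(out)) >
#'   psnr(255 * as.matrix(clean), 255 * as.matrix(noisy))
#' @export
denoise <- function(noisy, config = denoise_config(), reference = NULL) {
  if (!inherits(config, "denoise_config")) {
    stop(errorCondition("`config` must be a denoise_config",
                        class = c("lpwave_config_error", "error", "condition")))
  }
  img <- as_image_grid(noisy)
  beta <- NULL
  if (needs_reference(config)) {
    if (is.null(reference)) {
      stop(errorCondition(
        sprintf("threshold '%s' / shrink '%s' requires a reference image",
                config$threshold_method, config$shrink_method),
        class = c("lpwave_config_error", "error", "condition")))
    }
    ref <- as_image_grid(reference)
    if (!identical(dim(ref), dim(img))) {
      stop(errorCondition("reference and noisy image dimensions differ",
                          class = c("lpwave_config_error", "error", "condition")))
    }
    beta <- linear_prediction_factor(ref, img)
  }

  stage <- "decompose"
  result <- tryCatch({
    pyr <- decompose(img, config$wavelet, config$levels)
    stage <- "estimate_sigma"
    sigma <- estimate_sigma(pyr)$sigma
    n_image <- img$height * img$width
    applied <- list()

    stage <- "threshold/shrink"
    if (config$threshold_method == "bayes") {
      # per-subband threshold
      out_pyr <- pyr
      for (j in seq_len(pyr$levels)) {
        for (sb in c("HL", "LH", "HH")) {
          w <- pyr$details[[j]][[sb]]
          T_sb <- bayes_threshold(sigma, w)
          applied[[sprintf("level%d_%s", j, sb)]] <- as.numeric(T_sb)
          rule <- shrink_rule(config$shrink_method, as.numeric(T_sb),
                              alpha = config$alpha, beta = beta)
          out_pyr$details[[j]][[sb]] <- rule(w)
        }
      }
    } else if (config$threshold_method == "universal") {
      t_of <- function(w) {
        n <- if (config$n_convention == "image") n_image else length(w)
        universal_threshold(sigma, n, config$log_base)
      }
      if (config$n_convention == "image") {
        T_glob <- t_of(NULL)
        applied$global <- T_glob
        rule <- shrink_rule(config$shrink_method, T_glob,
                            alpha = config$alpha, beta = beta)
        out_pyr <- map_details(pyr, rule)
      } else {
        out_pyr <- pyr
        for (j in seq_len(pyr$levels)) {
          for (sb in c("HL", "LH", "HH")) {
            w <- pyr$details[[j]][[sb]]
            T_sb <- t_of(w)
            applied[[sprintf("level%d_%s", j, sb)]] <- T_sb
            rule <- shrink_rule(config$shrink_method, T_sb,
                                alpha = config$alpha, beta = beta)
            out_pyr$details[[j]][[sb]] <- rule(w)
          }
        }
      }
    } else {  # proposed: per-level threshold
      t_level <- vapply(seq_len(config$levels), function(j) {
        n <- n_image  # Eq. uses the signal length; per-subband handled below
        as.numeric(proposed_threshold(sigma, n, j, beta,
                                      log_base = config$log_base,
                                      eq13_parse = config$eq13_parse))
      }, numeric(1))
      if (config$n_convention == "subband") {
        out_pyr <- pyr
        for (j in seq_len(pyr$levels)) {
          for (sb in c("HL", "LH", "HH")) {
            w <- pyr$details[[j]][[sb]]
            T_sb <- as.numeric(proposed_threshold(sigma, length(w), j, beta,
                                                  log_base = config$log_base,
                                                  eq13_parse = config$eq13_parse))
            applied[[sprintf("level%d_%s", j, sb)]] <- T_sb
            rule <- shrink_rule(config$shrink_method, T_sb,
                                alpha = config$alpha, beta = beta)
            out_pyr$details[[j]][[sb]] <- rule(w)
          }
        }
      } else {
        applied$per_level <- t_level
        rule <- shrink_rule(config$shrink_method,
                            threshold = function(j) t_level[j],
                            alpha = config$alpha, beta = beta)
        out_pyr <- map_details(pyr, rule, per_level = TRUE)
      }
    }

    stage <- "reconstruct"
    rec <- reconstruct(out_pyr)
    if (config$clip_output) {
      rec <- image_grid(pmin(pmax(rec$pixels, 0), rec$L), rec$L)
    }
    attr(rec, "denoise_info") <- list(
      sigma = sigma,
      beta = if (is.null(beta)) NA_real_ else beta$beta,
      thresholds = applied,
      config = config
    )
    rec
  }, error = function(e) {
    if (inherits(e, "lpwave_config_error")) stop(e)
    stop(sprintf("denoise failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  result
}

# deterministic per-cell seed: independent, individually reproducible,
# kept below 2^31
cell_seed <- function(base_seed, image_index, variance, rep) {
  (as.numeric(base_seed) +
     image_index * 1000003 +
     (round(variance * 1e6) %% 65521) * 97 +
     rep * 1009) %% 2147483647
}

#' Run the denoising benchmark
#'
#' Full factorial over images x noise variances x methods x replicates.
#' Every method within a cell sees the *same* noisy realization (the
#' noise seed depends only on image, variance and replicate), so methods
#' are compared in a paired design.  Metrics are reported on the 0-255
#' scale.
#'
#' @param images An `image_grid` or (optionally named) list of them,
#'   normalized to `[0, 1]`.
#' @param variances Numeric vector of noise variances.
#' @param methods Named list of [denoise_config()]s; defaults to the
#'   three presets `visushrink`, `bayesshrink` and `proposed`.
#' @param reps Replicates per cell (>= 1).
#' @param seed Base seed for the deterministic seed schedule.
#' @param ssim_mode `"global"` or `"windowed"`.
#' @return A `data.frame` (class `benchmark_records`) with columns
#'   `image_id`, `method`, `noise_variance`, `replicate`, `seed`,
#'   `mse`, `psnr_db`, `ssim`.  A failed cell yields a row of `NA`
#'   metrics rather than aborting the run.
#' @export
run_benchmark <- function(images, variances = c(0.01, 0.02, 0.03, 0.04, 0.05),
                          methods = benchmark_methods(), reps = 1L, seed = 1L,
                          ssim_mode = "global") {
  if (inherits(images, "image_grid")) images <- list(images)
  if (!is.list(images) || length(images) == 0L) {
    stop("`images` must be a non-empty list of image_grids", call. = FALSE)
  }
  if (is.null(names(images)) || any(names(images) == "")) {
    names(images) <- sprintf("image_%d", seq_along(images))
  }
  if (length(variances) == 0L || any(variances <= 0)) {
    stop("`variances` must be positive", call. = FALSE)
  }
  if (!is.list(methods) || is.null(names(methods))) {
    stop("`methods` must be a named list of denoise_configs", call. = FALSE)
  }
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) stop("`reps` must be >= 1", call. = FALSE)

  rows <- list()
  for (i in seq_along(images)) {
    clean <- as_image_grid(images[[i]])
    for (v in variances) {
      for (r in seq_len(reps)) {
        s <- cell_seed(seed, i, v, r)
        noisy <- add_gaussian_noise(clean, v, seed = s)
        for (m in names(methods)) {
          rec <- tryCatch({
            den <- denoise(noisy, methods[[m]], reference = clean)
            rep_ <- metrics_report(clean, den, L = 255, ssim_mode = ssim_mode)
            list(mse = rep_$mse, psnr = rep_$psnr_db, ssim = rep_$ssim)
          }, error = function(e) {
            warning(sprintf("cell (%s, %s, v=%g, rep %d) failed: %s",
                            names(images)[i], m, v, r, conditionMessage(e)),
                    call. = FALSE)
            list(mse = NA_real_, psnr = NA_real_, ssim = NA_real_)
          })
          rows[[length(rows) + 1L]] <- data.frame(
            image_id = names(images)[i], method = m, noise_variance = v,
            replicate = r, seed = s, mse = rec$mse, psnr_db = rec$psnr,
            ssim = rec$ssim, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("benchmark_records", "data.frame")
  out
}

#' Standard benchmark method presets
#'
#' @param alpha Semi-soft weight forwarded to the configs.
#' @return Named list of [denoise_config()]s: `visushrink`
#'   (universal + soft), `bayesshrink` (bayes + soft) and `proposed`
#'   (proposed threshold + adaptive shrinkage).
#' @export
benchmark_methods <- function(alpha = 0.5) {
  list(
    visushrink  = denoise_config(threshold_method = "universal",
                                 shrink_method = "soft", alpha = alpha),
    bayesshrink = denoise_config(threshold_method = "bayes",
                                 shrink_method = "soft", alpha = alpha),
    proposed    = denoise_config(threshold_method = "proposed",
                                 shrink_method = "adaptive", alpha = alpha)
  )
}

#' Per-cell means of a benchmark run
#'
#' @param records Output of [run_benchmark()].
#' @return Data frame of mean `mse`, `psnr_db`, `ssim` per
#'   (image, method, variance) cell.
#' @export
summarize_benchmark <- function(records) {
  agg <- stats::aggregate(
    records[c("mse", "psnr_db", "ssim")],
    by = records[c("image_id", "method", "noise_variance")],
    FUN = mean
  )
  agg[order(agg$image_id, agg$method, agg$noise_variance), , drop = FALSE]
}

#' @export
print.benchmark_records <- function(x, ...) {
  s <- summarize_benchmark(x)
  for (img in unique(s$image_id)) {
    cat(sprintf("== %s ==\n", img))
    blk <- s[s$image_id == img, , drop = FALSE]
    vs <- sort(unique(blk$noise_variance))
    for (metric in c("mse", "psnr_db", "ssim")) {
      cat(sprintf("%s\n", toupper(metric)))
      hdr <- paste(sprintf("%9.3g", vs), collapse = " ")
      cat(sprintf("  %-12s %s\n", "variance", hdr))
      for (m in unique(blk$method)) {
        vals <- vapply(vs, function(v) {
          blk[blk$method == m & blk$noise_variance == v, metric][1]
        }, numeric(1))
        cat(sprintf("  %-12s %s\n", m,
                    paste(sprintf("%9.4g", vals), collapse = " ")))
      }
    }
  }
  invisible(x)
}
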