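#' Configuration of the Monte-Carlo speckle experiments
#'
#' Defines the ensembles used by the scripted experiments: constant-gray
#' clean images, a sweep of speckle variances, and the number of replicate
#' noisy images per (gray, variance) cell.  Every image of an experiment
#' receives its own sub-seed derived deterministically from `seed`, so runs
#' are reproducible bit-for-bit.
#'
#' @param clean_grays Clean gray levels (default `c(20, 30, 40, 50)`).
#' @param variances Speckle variances (default `seq(0.1, 1, by = 0.1)`).
#' @param reps Replicate images per cell (default 100; the full-scale study
#'   design is 2500).
#' @param image_size `c(height, width)` of each image (default 256 x 256).
#' @param seed Base seed (default 0).
#' @param family Noise family (default `"uniform"`).
#' @return Object of class `"experiment_config"`.
#' @export
experiment_config <- function(clean_grays = c(20, 30, 40, 50),
                              variances = seq(0.1, 1, by = 0.1),
                              reps = 100L, image_size = c(256L, 256L),
                              seed = 0L, family = "uniform") {
  reps <- as.integer(reps)
  if (reps < 1L) stop("`reps` must be >= 1", call. = FALSE)
  if (any(variances <= 0) || any(variances > 1))
    stop("`variances` must lie in (0, 1]", call. = FALSE)
  structure(list(clean_grays = clean_grays, variances = variances,
                 reps = reps, image_size = as.integer(image_size),
                 seed = as.integer(seed), family = family),
            class = "experiment_config")
}

# Deterministic sub-seed for image `rep` of cell (gray gi, variance vi).
# Kept well below 2^31.
cell_seed <- function(base, gi, vi, rep) {
  (base + 7919L * gi + 104729L * vi + rep) %% 2000000011L
}

# Iterate an ensemble cell, applying `fn(noisy, clean)` to each replicate
# and returning the list of results.
ensemble_apply <- function(cfg, gray, variance, fn, gi, vi,
                           clip = TRUE, quantize = TRUE) {
  clean <- constant_image(gray, cfg$image_size)
  lapply(seq_len(cfg$reps), function(rep) {
    sp <- speckle_spec(variance, family = cfg$family, clip = clip,
                       quantize = quantize,
                       seed = cell_seed(cfg$seed, gi, vi, rep))
    fn(add_speckle(clean, sp), clean)
  })
}

#' Ensemble average gray level versus speckle variance
#'
#' For each clean gray and each variance, generates `reps` noisy images and
#' reports the ensemble mean AGL with its standard error.  With clipping and
#' quantization on (the camera dialect) the AGL fluctuates around the clean
#' value for small variances and rises with variance once clipping and
#' singular pixels set in; with both off the AGL is flat (mean preservation
#' of multiplicative zero-mean noise).
#'
#' @param cfg An [experiment_config()].
#' @param clip,quantize Noise-dialect flags (defaults TRUE, TRUE).
#' @param csv Optional path to write the table as CSV.
#' @return Data frame with columns `gray`, `variance`, `agl`, `agl_se`.
#' @export
run_fig4 <- function(cfg = experiment_config(), clip = TRUE, quantize = TRUE,
                     csv = NULL) {
  rows <- list()
  for (gi in seq_along(cfg$clean_grays)) for (vi in seq_along(cfg$variances)) {
    agls <- unlist(ensemble_apply(cfg, cfg$clean_grays[gi], cfg$variances[vi],
                                  function(noisy, clean) average_gray(noisy),
                                  gi, vi, clip = clip, quantize = quantize))
    rows[[length(rows) + 1L]] <- data.frame(
      gray = cfg$clean_grays[gi], variance = cfg$variances[vi],
      agl = mean(agls), agl_se = sd(agls) / sqrt(length(agls)))
  }
  out <- do.call(rbind, rows)
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE)
  out
}

#' Ensemble singular-pixel fraction versus speckle variance
#'
#' Reports the mean fraction of singular pixels (noisy >= 2 x clean) per
#' variance.  By default the un-censored process is evaluated
#' (`clip = FALSE, quantize = FALSE`), for which the fraction is exactly 0
#' for variances up to 1/3 and follows the closed form
#' \eqn{P(n > 1) = (\sqrt{3v} - 1)/(2\sqrt{3v})} beyond under the uniform
#' dialect.
#'
#' @param cfg An [experiment_config()] (only the first clean gray is used).
#' @param clip,quantize Noise-dialect flags (defaults FALSE, FALSE).
#' @param csv Optional CSV output path.
#' @return Data frame with columns `gray`, `variance`, `fraction`, `fraction_se`.
#' @export
run_fig5 <- function(cfg = experiment_config(), clip = FALSE, quantize = FALSE,
                     csv = NULL) {
  gray <- cfg$clean_grays[1]
  rows <- lapply(seq_along(cfg$variances), function(vi) {
    fr <- unlist(ensemble_apply(cfg, gray, cfg$variances[vi],
                                singular_fraction, 1L, vi,
                                clip = clip, quantize = quantize))
    data.frame(gray = gray, variance = cfg$variances[vi],
               fraction = mean(fr), fraction_se = sd(fr) / sqrt(length(fr)))
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE)
  out
}

# Built-in method registry for the comparison harness.  Additional denoisers
# can be plugged in as named functions of one image.
default_methods <- function() {
  list(
    unprocessed = function(img) img,
    lee = function(img) lee_filter(img),
    amf = function(img) adaptive_median(img),
    pnlm = function(img) pnlm_denoise(img),
    pnlm_g = function(img) pnlm_g(img)$image
  )
}

#' Comparison table of despeckling methods
#'
#' For every variance, corrupts `reps` constant-gray images and runs each
#' method, reporting the ensemble mean AGL and SI (means over per-image
#' values) with standard errors — the layout of the method-comparison table.
#'
#' @param cfg An [experiment_config()] (first clean gray is used; default 40
#'   when the config default is kept).
#' @param methods Named list of functions `function(img) -> img`; defaults to
#'   the built-in registry (`unprocessed`, `lee`, `amf`, `pnlm`, `pnlm_g`).
#'   External denoisers can be added to the list.
#' @param gray Clean gray level; default `cfg$clean_grays` closest to 40.
#' @param csv Optional CSV output path.
#' @return Data frame with columns `variance`, `method`, `agl`, `agl_se`,
#'   `si`, `si_se`.
#' @export
run_table1 <- function(cfg = experiment_config(), methods = default_methods(),
                       gray = NULL, csv = NULL) {
  if (is.null(names(methods)) || any(names(methods) == ""))
    stop("`methods` must be a named list of functions", call. = FALSE)
  if (is.null(gray)) gray <- cfg$clean_grays[which.min(abs(cfg$clean_grays - 40))]
  gi <- which(cfg$clean_grays == gray)[1]
  if (is.na(gi)) gi <- 1L
  rows <- list()
  for (vi in seq_along(cfg$variances)) {
    per_image <- ensemble_apply(cfg, gray, cfg$variances[vi], function(noisy, clean) {
      vapply(methods, function(f) {
        out <- f(noisy)
        c(agl = average_gray(out), si = speckle_index(out))
      }, numeric(2))
    }, gi, vi)
    for (m in names(methods)) {
      agls <- vapply(per_image, function(x) x["agl", m], numeric(1))
      sis <- vapply(per_image, function(x) x["si", m], numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        variance = cfg$variances[vi], method = m,
        agl = mean(agls), agl_se = sd(agls) / sqrt(length(agls)),
        si = mean(sis), si_se = sd(sis) / sqrt(length(sis)))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE)
  out
}

#' Gray-value recovery sweep
#'
#' Runs the full PNLM-G pipeline over a (clean gray) x (variance) grid of
#' noisy ensembles and scores each image as recovered when its restored AGL
#' lies within `tol` of the clean gray.  The headline number is the overall
#' recovered percentage.
#'
#' @param cfg An [experiment_config()].
#' @param tol Recovery tolerance in gray levels (default 0.05).
#' @param params,policy Pipeline parameters passed to [pnlm_g()].
#' @param csv Optional CSV output path for the per-cell table.
#' @return List with `per_cell` data frame (`gray`, `variance`, `recovered`,
#'   `reps`, `mean_abs_err`) and scalar `recovery_rate` (percent).
#' @export
run_recovery_sweep <- function(cfg = experiment_config(reps = 40L), tol = 0.05,
                               params = pnlm_params(), policy = mark_policy(),
                               csv = NULL) {
  rows <- list()
  for (gi in seq_along(cfg$clean_grays)) for (vi in seq_along(cfg$variances)) {
    gray <- cfg$clean_grays[gi]
    errs <- unlist(ensemble_apply(cfg, gray, cfg$variances[vi],
      function(noisy, clean) {
        abs(average_gray(pnlm_g(noisy, params, policy)$image) - gray)
      }, gi, vi))
    rows[[length(rows) + 1L]] <- data.frame(
      gray = gray, variance = cfg$variances[vi],
      recovered = sum(errs <= tol), reps = length(errs),
      mean_abs_err = mean(errs))
  }
  per_cell <- do.call(rbind, rows)
  if (!is.null(csv)) write.csv(per_cell, csv, row.names = FALSE)
  list(per_cell = per_cell,
       recovery_rate = 100 * sum(per_cell$recovered) / sum(per_cell$reps))
}
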