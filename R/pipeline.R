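#' Configuration for the experiment grid
#'
#' Describes the pretreatment x selector x model grid mirrored from the
#' study's report tables, plus every tunable the stages expose. Reduced
#' grids (fewer hyperparameter rungs, fewer frog iterations) run the same
#' code paths faster and are used by the test suite.
#'
#' @param preprocessors subset of `c("sg", "normalization", "snv")`.
#' @param selectors subset of `c("spa", "frog")`.
#' @param models subset of `c("plsr", "svr", "lssvm")`.
#' @param n_train SPXY calibration-set size (count or fraction); default
#'   180/230 of n.
#' @param seed master seed (folds, frog, SVR/LSSVM grid CV).
#' @param plsr_components PLSR latent components.
#' @param svr_c,svr_gamma,svr_epsilon SVR hyperparameter grid.
#' @param lssvm_gamma,lssvm_sigma2 LSSVM hyperparameter grid.
#' @param spa_min_vars,spa_max_vars SPA subset-size range.
#' @param frog_n_iter,frog_q_init,frog_final_k random-frog controls.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @param split_on `"raw"` (default) or `"preprocessed"`: spectra the SPXY
#'   split distances are computed on.
#' @return Object of class `grid_config`.
#' @export
grid_config <- function(preprocessors = c("sg", "normalization", "snv"),
                        selectors = c("spa", "frog"),
                        models = c("plsr", "svr", "lssvm"),
                        n_train = 180 / 230, seed = 1L,
                        plsr_components = 4L,
                        svr_c = 10^(-3:3), svr_gamma = 10^(-3:3),
                        svr_epsilon = 0.01,
                        lssvm_gamma = 10^(-3:3), lssvm_sigma2 = 10^(-3:3),
                        spa_min_vars = 2L, spa_max_vars = NULL,
                        frog_n_iter = 1000L, frog_q_init = 5L,
                        frog_final_k = "auto",
                        sg_window = 11L, sg_polyorder = 2L,
                        split_on = "raw") {
  if (!length(preprocessors) || !length(selectors) || !length(models))
    stop("preprocessors, selectors and models must be non-empty")
  structure(as.list(environment()), class = "grid_config")
}

# Paper table row order within each model block.
grid_combos <- function(cfg) {
  all_combos <- list(c("sg", "spa"), c("sg", "frog"),
                     c("normalization", "frog"), c("normalization", "spa"),
                     c("snv", "frog"), c("snv", "spa"))
  Filter(function(cb) cb[1L] %in% cfg$preprocessors &&
           cb[2L] %in% cfg$selectors, all_combos)
}

fit_grid_model <- function(model, Xtr, ytr, cfg) {
  switch(model,
         plsr = fit_plsr(Xtr, ytr, cfg$plsr_components),
         svr = fit_svr(Xtr, ytr, cfg$svr_c, cfg$svr_gamma, cfg$svr_epsilon,
                       seed = cfg$seed),
         lssvm = fit_lssvm(Xtr, ytr, cfg$lssvm_gamma, cfg$lssvm_sigma2,
                           seed = cfg$seed),
         stop("unknown model: ", model))
}

#' Run the pretreatment x selector x model grid
#'
#' For each pretreatment and wavelength selector: pretreat the spectra,
#' split by SPXY, run the selector on the calibration spectra only, fit
#' each chemometric model on the selected channels (hyperparameters by
#' seeded cross-validation) and evaluate on both sets. With the full
#' default configuration this yields 18 rows -- three 6-row blocks
#' mirroring the study's PLSR, SVR and LSSVM tables. The attached
#' `"manifest"` attribute records the seed and configuration so a rerun is
#' byte-identical.
#'
#' @param data a [spectra_set()] of raw spectra.
#' @param cfg a [grid_config()].
#' @param split optional [split_indices()]; computed by [spxy_split()] when
#'   omitted.
#' @return Data frame with columns `model`, `pre_processing`, `selector`,
#'   `vn`, `r_c`, `rmse_c`, `r_p`, `rmse_p` and attribute `manifest`.
#' @export
run_grid <- function(data, cfg = grid_config(), split = NULL) {
  validate_spectra_set(data)
  stopifnot(inherits(cfg, "grid_config"))
  X_raw <- data$reflectance
  y <- data$target
  labels <- c(sg = "SG", normalization = "Normalization", snv = "SNV",
              spa = "SPA", frog = "RF")
  combos <- grid_combos(cfg)
  if (!length(combos)) stop("empty grid: no preprocessor/selector combos")

  rows <- list()
  for (model in cfg$models) {
    for (cb in combos) {
      pre <- cb[1L]; selector <- cb[2L]
      coord <- sprintf("(%s + %s, %s)", labels[[pre]], labels[[selector]],
                       model)
      res <- tryCatch({
        Xp <- preprocess_spectra(X_raw, pre, sg_window = cfg$sg_window,
                                 sg_polyorder = cfg$sg_polyorder)
        Xsplit <- if (identical(cfg$split_on, "preprocessed")) Xp else X_raw
        sp <- if (is.null(split)) spxy_split(Xsplit, y, cfg$n_train) else split
        Xtr <- Xp[sp$train, , drop = FALSE]
        sel <- if (selector == "spa") {
          spa_select(Xtr, y[sp$train], cfg$spa_min_vars, cfg$spa_max_vars)
        } else {
          random_frog_select(Xtr, y[sp$train], n_iter = cfg$frog_n_iter,
                             q_init = cfg$frog_q_init, seed = cfg$seed,
                             final_k = cfg$frog_final_k)
        }
        cols <- sel$selected
        fit <- fit_grid_model(model, Xtr[, cols, drop = FALSE],
                              y[sp$train], cfg)
        Xte <- Xp[sp$test, cols, drop = FALSE]
        ev <- eval_report(y[sp$train],
                          predict(fit, Xtr[, cols, drop = FALSE]),
                          y[sp$test], predict(fit, Xte))
        data.frame(model = model,
                   pre_processing = paste(labels[[pre]], "+",
                                          labels[[selector]]),
                   selector = selector, vn = length(cols),
                   r_c = ev$r_c, rmse_c = ev$rmse_c,
                   r_p = ev$r_p, rmse_p = ev$rmse_p)
      }, error = function(e) {
        stop(sprintf("grid stage failed at %s: %s", coord,
                     conditionMessage(e)), call. = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  report <- do.call(rbind, rows)
  attr(report, "manifest") <- list(seed = cfg$seed, config = unclass(cfg),
                                   package_version =
                                     as.character(utils::packageVersion("cottonir")))
  report
}

#' Compare the best chemometric row with the best network row
#'
#' Picks the maximum-R_P row of each report (ties broken by lower RMSE_P)
#' and returns them side by side, recording which wins on this dataset. No
#' claim is made beyond the data at hand.
#'
#' @param grid_report output of [run_grid()].
#' @param ablation_report output of [run_activation_ablation()].
#' @return List with `best_chemometric`, `best_net`, and `net_wins`
#'   (logical: strictly higher R_P, RMSE_P tie-break).
#' @export
best_model_comparison <- function(grid_report, ablation_report) {
  pick <- function(report) {
    if (is.null(report) || !nrow(report)) stop("empty report")
    ord <- order(-report$r_p, report$rmse_p)
    report[ord[1L], , drop = FALSE]
  }
  bc <- pick(grid_report)
  bn <- pick(ablation_report)
  net_wins <- bn$r_p > bc$r_p ||
    (bn$r_p == bc$r_p && bn$rmse_p < bc$rmse_p)
  list(best_chemometric = bc, best_net = bn, net_wins = net_wins)
}
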