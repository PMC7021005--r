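#' Configuration of the full perturbation study
#'
#' Defines the perturbation grid (leaf-tip offsets at a uniform step
#' crossed with leaf-tip widths), the clinical baseline model, the gamma
#' criteria presets, the QA noise/replication settings and the master
#' seed.  The clinical parameters must be contained in the grid.
#'
#' @param offsets_mm sorted, uniformly spaced leaf-tip offsets, mm.
#' @param widths_mm leaf-tip widths, mm.
#' @param clinical_offset_mm,clinical_width_mm the clinical model.
#' @param leaf_transmission intraleaf leakage fraction shared by all
#'   models.
#' @param tip_rule tip-transmission rule, see [beam_model()].
#' @param criteria list of [gamma_criteria()] presets.
#' @param noise_sigma_pct diode-array noise, % of maximum.
#' @param n_replicates noise-replicate "deliveries" per plan.
#' @param master_seed integer master seed; every stream is derived from it
#'   via [split_seed()]-style fan-out.
#' @param grid fluence [grid_spec()].
#' @param kernel [kernel_params()].
#' @param array [array_spec()] geometry (its seed/noise fields are
#'   overridden per replicate from this config).
#' @param eval_spacing_mm resolution of the calculated (evaluated)
#'   distribution on the array plane used in gamma analysis, mm.
#' @param out_dir optional output directory for [run_study()] CSVs.
#' @return An object of class `study_config`.
#' @export
study_config <- function(offsets_mm = seq(-2, 2, by = 0.5),
                         widths_mm = c(2.5, 4.5, 6.0),
                         clinical_offset_mm = -0.5,
                         clinical_width_mm = 4.5,
                         leaf_transmission = 0.005,
                         tip_rule = "sqrt",
                         criteria = list(gamma_criteria(2, 2),
                                         gamma_criteria(3, 3)),
                         noise_sigma_pct = 0.5,
                         n_replicates = 20,
                         master_seed = 1L,
                         grid = grid_spec(),
                         kernel = kernel_params(),
                         array = array_spec(),
                         eval_spacing_mm = 1,
                         out_dir = NULL) {
  stopifnot(length(offsets_mm) >= 1, !is.unsorted(offsets_mm),
            length(widths_mm) >= 1, n_replicates >= 1,
            noise_sigma_pct >= 0, eval_spacing_mm > 0)
  if (length(offsets_mm) > 1) {
    st <- diff(offsets_mm)
    if (max(st) - min(st) > 1e-9) stop("offsets_mm must be uniformly spaced")
  }
  if (!any(abs(offsets_mm - clinical_offset_mm) < 1e-9) ||
      !any(abs(widths_mm - clinical_width_mm) < 1e-9))
    stop("the clinical model must be contained in the perturbation grid")
  structure(list(offsets_mm = offsets_mm, widths_mm = widths_mm,
                 clinical_offset_mm = clinical_offset_mm,
                 clinical_width_mm = clinical_width_mm,
                 leaf_transmission = leaf_transmission,
                 tip_rule = tip_rule, criteria = criteria,
                 noise_sigma_pct = noise_sigma_pct,
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed),
                 grid = grid, kernel = kernel, array = array,
                 eval_spacing_mm = eval_spacing_mm,
                 out_dir = out_dir), class = "study_config")
}

#' Clinical beam model of a study configuration
#' @param config a [study_config()].
#' @return A [beam_model()].
#' @export
clinical_model <- function(config) {
  beam_model(config$clinical_offset_mm, config$clinical_width_mm,
             config$leaf_transmission, config$tip_rule)
}

#' Build the perturbation model grid
#'
#' Cartesian product of the configured offsets and widths, all sharing the
#' configured transmission and tip rule, with deterministic model ids.
#'
#' @param config a [study_config()].
#' @return list of [beam_model()]s (offsets vary fastest).
#' @export
build_model_grid <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (length(config$offsets_mm) == 0 || length(config$widths_mm) == 0)
    stop("empty offset or width list")
  grid <- list()
  for (w in config$widths_mm) for (d in config$offsets_mm)
    grid[[length(grid) + 1L]] <-
      beam_model(d, w, config$leaf_transmission, config$tip_rule)
  grid
}

#' Recalculate ROI doses over the model grid (sensitivity analysis)
#'
#' Recalculates every plan of the suite on every model of the perturbation
#' grid (plans are never re-generated per model) and reports the
#' TLD-ROI mean doses and their percent difference from the clinical
#' model: `pct_diff = 100 * (D_model - D_clinical) / D_clinical`.
#'
#' @param config a [study_config()].
#' @param suite optional plan suite; defaults to
#'   `generate_plan_suite(config$master_seed)`.
#' @param phantom a [phantom_spec()].
#' @param verbose emit per-plan progress messages.
#' @return data frame with one row per (plan, model, ROI): `plan_id`,
#'   `technique`, `model_id`, `offset_mm`, `width_mm`, `roi`, `gradient`,
#'   `dose`, `pct_diff`.
#' @export
run_sensitivity <- function(config, suite = NULL,
                            phantom = default_phantom(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(suite)) suite <- generate_plan_suite(config$master_seed, phantom)
  rois <- tld_rois(phantom)
  pts <- do.call(rbind, lapply(seq_len(nrow(rois)), function(i)
    cbind(.roi_sample_points(rois$x_mm[i], rois$z_mm[i], rois$radius_mm[i]),
          roi = rois$roi[i])))
  models <- build_model_grid(config)
  clin <- clinical_model(config)
  out <- vector("list", length(suite) * length(models))
  k <- 0L
  for (plan in suite) {
    if (verbose) message("sensitivity: ", plan$plan_id)
    roi_dose <- function(model) {
      d <- composite_point_dose(plan, model, pts, phantom,
                                config$kernel, config$grid)
      tapply(d, pts$roi, mean)[rois$roi]
    }
    dc <- roi_dose(clin)
    if (any(dc <= 0))
      stop("clinical ROI dose is zero for plan ", plan$plan_id,
           ": broken plan generator")
    for (model in models) {
      dm <- if (model$model_id == clin$model_id) dc else roi_dose(model)
      k <- k + 1L
      out[[k]] <- data.frame(
        plan_id = plan$plan_id, technique = plan$technique,
        model_id = model$model_id,
        offset_mm = model$leaf_tip_offset_mm,
        width_mm = model$leaf_tip_width_mm,
        roi = rois$roi, gradient = rois$gradient,
        dose = as.numeric(dm),
        pct_diff = 100 * (as.numeric(dm) - as.numeric(dc)) / as.numeric(dc))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulated QA comparisons and ROC detectability analysis
#'
#' For every plan, the "delivered" dose is the clinical (truth) model
#' sampled on the diode array with seeded measurement-noise replicates;
#' the "calculated" dose is each candidate model (the offset sweep at the
#' clinical leaf-tip width) evaluated on the array plane.  Gamma pass
#' rates are computed for every criteria preset, records are labeled
#' against the clinical model, and one ROC curve is built per offset
#' deviation magnitude and criteria (plus a pooled curve over all
#' positives).
#'
#' @inheritParams run_sensitivity
#' @return list with `records` (one row per plan x candidate x replicate x
#'   criteria), `roc_summary` (data frame `offset_dev_mm`, `criteria`,
#'   `auc`, `n_pos`, `n_neg`; `offset_dev_mm = NA` marks the pooled
#'   curve), and `curves` (named list of [roc_curve()] objects).
#' @export
run_detectability <- function(config, suite = NULL,
                              phantom = default_phantom(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(suite)) suite <- generate_plan_suite(config$master_seed, phantom)
  clin <- clinical_model(config)
  cand <- lapply(config$offsets_mm, function(d)
    beam_model(d, config$clinical_width_mm, config$leaf_transmission,
               config$tip_rule))
  xs <- seq(-config$array$extent_mm, config$array$extent_mm,
            by = config$eval_spacing_mm)
  eval_grid <- grid_spec(c(min(xs), min(xs)), config$eval_spacing_mm,
                         length(xs), length(xs))
  dio <- .array_positions(config$array)
  di <- match(round(dio$x, 9), round(xs, 9))
  if (anyNA(di)) stop("diode pitch must be a multiple of eval_spacing_mm")
  ref_xy <- data.frame(x_mm = rep(dio$x, times = length(dio$y)),
                       y_mm = rep(dio$y, each = length(dio$x)))
  # restrict the search so interpolation stays inside the evaluated grid
  margin <- max(vapply(config$criteria, function(cr)
    3 * cr$dta_mm, numeric(1)))
  inner <- abs(ref_xy$x_mm) <= config$array$extent_mm - margin &
    abs(ref_xy$y_mm) <= config$array$extent_mm - margin
  ref_xy <- ref_xy[inner, , drop = FALSE]
  rec <- list(); rk <- 0L
  for (pi in seq_along(suite)) {
    plan <- suite[[pi]]
    if (verbose) message("detectability: ", plan$plan_id)
    truth_fine <- plane_dose(plan, clin, xs, xs, phantom,
                             config$kernel, config$grid)
    truth_ref <- as.vector(truth_fine[di, di])[inner]
    sd_abs <- config$noise_sigma_pct / 100 * max(truth_ref)
    meas <- matrix(0, length(truth_ref), config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      set.seed(split_seed(config$master_seed, pi * 1000L + r))
      meas[, r] <- pmax(0, truth_ref +
                          stats::rnorm(length(truth_ref), 0, sd_abs))
    }
    for (cm in cand) {
      pred_fine <- if (cm$model_id == clin$model_id) truth_fine else
        plane_dose(plan, cm, xs, xs, phantom, config$kernel, config$grid)
      emap <- dose_map(eval_grid, pred_fine)
      for (cr in config$criteria) {
        off <- .gamma_offsets(cr, 0.1, 3)
        E <- .gamma_eval_matrix(ref_xy, emap, off)
        for (r in seq_len(config$n_replicates)) {
          dref <- meas[, r]
          dmax <- max(dref)
          mask <- dref >= cr$low_dose_threshold_pct / 100 * dmax
          dd_abs <- cr$dose_pct / 100 * dmax
          coarse <- .gamma_from_matrix(dref[mask], E[mask, , drop = FALSE],
                                       off, dd_abs)
          g <- .gamma_refine(ref_xy[mask, , drop = FALSE], dref[mask],
                             emap, cr, off, coarse, dd_abs, 0.1)
          rk <- rk + 1L
          rec[[rk]] <- data.frame(
            plan_id = plan$plan_id, technique = plan$technique,
            model_id = cm$model_id, offset_mm = cm$leaf_tip_offset_mm,
            width_mm = cm$leaf_tip_width_mm, criteria = cr$label,
            replicate = r,
            replicate_seed = split_seed(config$master_seed, pi * 1000L + r),
            n_evaluated = sum(mask),
            pass_rate = 100 * mean(g <= 1 + 1e-9))
        }
      }
    }
  }
  records <- do.call(rbind, rec)
  rownames(records) <- NULL
  records <- label_records(records, clin)
  detectability_summary(records, config)
}

#' Summarize labeled QA records into per-deviation ROC curves
#'
#' @param records labeled records (see [run_detectability()]).
#' @param config a [study_config()].
#' @return see [run_detectability()].
#' @export
detectability_summary <- function(records, config) {
  clin_off <- config$clinical_offset_mm
  records$offset_dev_mm <- abs(records$offset_mm - clin_off)
  mags <- sort(unique(records$offset_dev_mm[records$label == "positive"]))
  curves <- list()
  summ <- list(); k <- 0L
  for (cr in config$criteria) {
    rc <- records[records$criteria == cr$label, , drop = FALSE]
    for (m in mags) {
      sub <- rc[rc$label == "negative" | rc$offset_dev_mm == m, , drop = FALSE]
      roc <- roc_curve(sub)
      key <- sprintf("dev%.1fmm_%s", m, cr$label)
      curves[[key]] <- roc
      k <- k + 1L
      summ[[k]] <- data.frame(offset_dev_mm = m, criteria = cr$label,
                              auc = roc$auc, n_pos = roc$n_pos,
                              n_neg = roc$n_neg)
    }
    roc <- roc_curve(rc)
    curves[[sprintf("pooled_%s", cr$label)]] <- roc
    k <- k + 1L
    summ[[k]] <- data.frame(offset_dev_mm = NA_real_, criteria = cr$label,
                            auc = roc$auc, n_pos = roc$n_pos,
                            n_neg = roc$n_neg)
  }
  list(records = records, roc_summary = do.call(rbind, summ),
       curves = curves)
}

#' Central-axis sensitivity of a single open field to the leaf-tip offset
#'
#' Computes the isocenter dose of a square open field under the clinical
#' model and under the clinical offset +/- 1 mm, and reports the mean
#' relative change per mm of offset.  Used to demonstrate that open
#' fields are nearly insensitive to the leaf-tip model.
#'
#' @param config a [study_config()].
#' @param size_mm field size.
#' @param phantom a [phantom_spec()].
#' @return list with `doses` (data frame `offset_mm`, `dose`) and
#'   `pct_per_mm` (mean |relative change| per mm of offset, percent).
#' @export
open_field_sensitivity <- function(config, size_mm = 100,
                                   phantom = default_phantom()) {
  plan <- open_field_plan(size_mm)
  pt <- data.frame(x_mm = 0, y_mm = 0, z_mm = 0)
  offs <- config$clinical_offset_mm + c(-1, 0, 1)
  d <- vapply(offs, function(o)
    composite_point_dose(plan,
                         beam_model(o, config$clinical_width_mm,
                                    config$leaf_transmission,
                                    config$tip_rule),
                         pt, phantom, config$kernel, config$grid),
    numeric(1))
  list(doses = data.frame(offset_mm = offs, dose = d),
       pct_per_mm = 100 * (d[3] - d[1]) / (2 * d[2]))
}

#' Boxplot-style summary of the sensitivity table
#'
#' Median and quartiles of the percent dose difference per
#' (offset, technique, ROI) at the clinical leaf-tip width; the analog of
#' the study's per-ROI boxplot panels.
#'
#' @param sens sensitivity table from [run_sensitivity()].
#' @param config a [study_config()].
#' @return data frame `offset_mm`, `technique`, `roi`, `median`, `q1`,
#'   `q3`, `n`.
#' @export
sensitivity_summary <- function(sens, config) {
  s <- sens[abs(sens$width_mm - config$clinical_width_mm) < 1e-9, ,
            drop = FALSE]
  agg <- function(f) stats::aggregate(
    pct_diff ~ offset_mm + technique + roi, data = s, FUN = f)
  med <- agg(stats::median)
  q1 <- agg(function(x) stats::quantile(x, 0.25))
  q3 <- agg(function(x) stats::quantile(x, 0.75))
  n <- agg(length)
  out <- med
  names(out)[names(out) == "pct_diff"] <- "median"
  out$q1 <- q1$pct_diff; out$q3 <- q3$pct_diff; out$n <- n$pct_diff
  out[order(out$roi, out$technique, out$offset_mm), ]
}

#' Run the full in-silico study
#'
#' Generates the plan suite, runs the sensitivity analysis over the full
#' perturbation grid, runs the QA detectability analysis, and (when
#' `config$out_dir` is set) writes all result tables and a run manifest
#' as CSV/DCF text files.  Everything is deterministic under the master
#' seed.
#'
#' @param config a [study_config()].
#' @param phantom a [phantom_spec()].
#' @param verbose emit stage progress messages.
#' @return list with `suite_manifest`, `sensitivity`,
#'   `sensitivity_summary`, `detectability` (see [run_detectability()]),
#'   and `open_field` (see [open_field_sensitivity()]).
#' @export
run_study <- function(config = study_config(), phantom = default_phantom(),
                      verbose = TRUE) {
  stopifnot(inherits(config, "study_config"))
  if (verbose) message("generating plan suite (seed ", config$master_seed, ")")
  suite <- generate_plan_suite(config$master_seed, phantom)
  sens <- run_sensitivity(config, suite, phantom, verbose = verbose)
  det <- run_detectability(config, suite, phantom, verbose = verbose)
  ofs <- open_field_sensitivity(config, phantom = phantom)
  res <- list(suite_manifest = suite_manifest(suite),
              sensitivity = sens,
              sensitivity_summary = sensitivity_summary(sens, config),
              detectability = det,
              open_field = ofs)
  if (!is.null(config$out_dir)) write_study_outputs(res, config)
  res
}

#' Write study outputs as text tables
#'
#' @param res result list from [run_study()].
#' @param config a [study_config()].
#' @return the output directory, invisibly.
#' @export
write_study_outputs <- function(res, config) {
  dir <- config$out_dir
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                       row.names = FALSE)
  w(res$suite_manifest, "suite_manifest.csv")
  w(res$sensitivity, "sensitivity.csv")
  w(res$sensitivity_summary, "sensitivity_summary.csv")
  w(res$detectability$records, "qa_records.csv")
  w(res$detectability$roc_summary, "roc_summary.csv")
  for (nm in names(res$detectability$curves)) {
    safe <- gsub("[^A-Za-z0-9._-]+", "_", nm)
    w(res$detectability$curves[[nm]]$curve, sprintf("roc_curve_%s.csv", safe))
  }
  manifest <- data.frame(
    package = "mlcqa",
    version = as.character(utils::packageVersion("mlcqa")),
    master_seed = config$master_seed,
    n_plans = nrow(res$suite_manifest),
    n_models = length(config$offsets_mm) * length(config$widths_mm),
    offsets_mm = paste(config$offsets_mm, collapse = ";"),
    widths_mm = paste(config$widths_mm, collapse = ";"),
    clinical_offset_mm = config$clinical_offset_mm,
    clinical_width_mm = config$clinical_width_mm,
    noise_sigma_pct = config$noise_sigma_pct,
    n_replicates = config$n_replicates,
    plan_seeds = paste(res$suite_manifest$seed, collapse = ";"),
    replicate_seeds = paste(
      range(res$detectability$records$replicate_seed), collapse = ".."))
  write.dcf(manifest, file.path(dir, "manifest.dcf"))
  invisible(dir)
}
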