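#' Write / read beam-model parameter files
#'
#' Beam models are stored as Debian-control-style key/value text with the
#' keys `model_id`, `leaf_tip_offset_mm`, `leaf_tip_width_mm`,
#' `leaf_transmission` and `tip_rule`; `read_beam_model` rebuilds the
#' model (re-deriving the tip transmission from the rule).
#'
#' @param model a [beam_model()].
#' @param path file path.
#' @return `write_beam_model` returns `path` invisibly; `read_beam_model`
#'   a [beam_model()].
#' @export
write_beam_model <- function(model, path) {
  stopifnot(inherits(model, "beam_model"))
  df <- data.frame(model_id = model$model_id,
                   leaf_tip_offset_mm = model$leaf_tip_offset_mm,
                   leaf_tip_width_mm = model$leaf_tip_width_mm,
                   leaf_transmission = model$leaf_transmission,
                   tip_rule = model$tip_rule)
  write.dcf(df, path)
  invisible(path)
}

#' @rdname write_beam_model
#' @export
read_beam_model <- function(path) {
  d <- read.dcf(path)
  beam_model(as.numeric(d[1, "leaf_tip_offset_mm"]),
             as.numeric(d[1, "leaf_tip_width_mm"]),
             as.numeric(d[1, "leaf_transmission"]),
             tip_rule = unname(d[1, "tip_rule"]),
             model_id = unname(d[1, "model_id"]))
}

#' Serialize / restore a treatment plan as a delimited table
#'
#' One row per (beam, segment, leaf pair) with nominal leaf positions, MU
#' and gantry angle; `read_plan` reconstructs the `treatment_plan`
#' object (without its generator spec).
#'
#' @param plan a `treatment_plan`.
#' @param path file path.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "treatment_plan"))
  rows <- list(); k <- 0L
  for (b in seq_along(plan$beams)) {
    beam <- plan$beams[[b]]
    for (s in seq_along(beam$segments)) {
      seg <- beam$segments[[s]]
      k <- k + 1L
      rows[[k]] <- cbind(data.frame(plan_id = plan$plan_id,
                                    technique = plan$technique,
                                    beam_index = b, segment_index = s,
                                    gantry_deg = seg$gantry_deg,
                                    mu = seg$mu),
                         seg$aperture)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  d <- utils::read.csv(path)
  beams <- list()
  for (b in sort(unique(d$beam_index))) {
    db <- d[d$beam_index == b, , drop = FALSE]
    segs <- lapply(sort(unique(db$segment_index)), function(s) {
      ds <- db[db$segment_index == s, , drop = FALSE]
      mlc_segment(ds[, c("pair_index", "y_low_mm", "y_high_mm",
                         "left_pos_mm", "right_pos_mm")],
                  mu = ds$mu[1], gantry_deg = ds$gantry_deg[1])
    })
    beams[[length(beams) + 1L]] <- list(gantry_deg = db$gantry_deg[1],
                                        segments = segs)
  }
  structure(list(plan_id = d$plan_id[1], technique = d$technique[1],
                 beams = beams,
                 total_mu = sum(vapply(beams, function(bb)
                   sum(vapply(bb$segments, `[[`, numeric(1), "mu")),
                   numeric(1))),
                 spec = NULL),
            class = "treatment_plan")
}

#' Suite manifest table
#'
#' @param suite list of `treatment_plan`s from [generate_plan_suite()].
#' @return data frame `plan_id`, `technique`, `n_beams_or_arcs`,
#'   `total_mu`, `seed`.
#' @export
suite_manifest <- function(suite) {
  do.call(rbind, lapply(suite, function(p)
    data.frame(plan_id = p$plan_id, technique = p$technique,
               n_beams_or_arcs = p$spec$n_beams_or_arcs,
               total_mu = p$total_mu, seed = p$spec$seed)))
}
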