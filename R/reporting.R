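# Contrast-dependent-bias summaries and report rendering.

#' Contrast-dependent bias per condition
#'
#' The CDB is the ratio of the high-contrast (test) grating's speed at the
#' PSE to the reference speed. The test grating always has the higher
#' contrast, so no re-labeling is needed: `cdb = mean_pse / v_ref`. Values
#' below 1 mean that lowering contrast lowered perceived speed (the Thompson
#' effect direction).
#'
#' @param table a `pse_table` (see [pse_summary()]).
#' @return a data frame: condition_id, v_ref, contrast_pair, cdb, sem (the
#'   standard error of the CDB over staircases).
#' @export
compute_cdb <- function(table) {
  check_table(table)
  data.frame(
    condition_id = table$condition_id,
    v_ref = table$v_ref,
    contrast_pair = sprintf("%g%%/%g%%", 100 * table$c_ref, 100 * table$c_test),
    cdb = table$mean_pse / table$v_ref,
    sem = sqrt(table$pse_var / table$n_staircases) / table$v_ref,
    stringsAsFactors = FALSE
  )
}

#' Model-predicted CDB per condition
#'
#' Overlay values for the report: `predict_pse(condition) / v_ref`, the same
#' prediction path used by the fitter (no separate formula).
#'
#' @param observer an [observer_spec()] (e.g. a fit's `$observer`, or a
#'   ground-truth generator).
#' @param conditions a conditions data frame (see [build_design()]).
#' @return a data frame: condition_id, v_ref, contrast_pair, cdb.
#' @export
predict_cdb <- function(observer, conditions) {
  pred <- vapply(seq_len(nrow(conditions)), function(i) {
    predict_pse(observer, conditions[i, ])
  }, numeric(1))
  data.frame(
    condition_id = conditions$condition_id,
    v_ref = conditions$v_ref,
    contrast_pair = sprintf("%g%%/%g%%", 100 * conditions$c_ref,
                            100 * conditions$c_test),
    cdb = pred / conditions$v_ref,
    stringsAsFactors = FALSE
  )
}

#' Serialize a fit result to JSON
#'
#' Parameters with units, the residual table and convergence diagnostics.
#'
#' @param fit a `speed_fit`.
#' @param path optional output path.
#' @return the JSON string, invisibly when written to a file.
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "speed_fit"))
  doc <- list(
    schema_version = "1.0",
    variant = if (is.null(fit$ratio)) "bayesian" else "combined",
    units = list(slope = "1/(deg/s)", g = "deg/s", speed = "deg/s"),
    knot_speeds = fit$observer$prior$knot_speeds,
    prior_slopes = fit$observer$prior$knot_slopes,
    likelihood_g = fit$observer$likelihood$knot_g,
    contrast = unclass(fit$observer$likelihood$contrast),
    ratio = if (is.null(fit$ratio)) NULL else unclass(fit$ratio),
    spatial_frequency = fit$observer$spatial_frequency,
    sse = fit$sse, r2 = fit$r2,
    converged = fit$converged, best_start = fit$best_start,
    logLik = fit$logLik,
    residual_table = fit$residual_table
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                         null = "null", dataframe = "columns")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Render a report for a dataset and fitted models
#'
#' Writes a deterministic file set to `out_dir`: a CDB-versus-speed figure
#' (one panel per contrast pair, error bars over staircases, one overlay
#' line per fit), a model-components figure (reconstructed prior, g(v),
#' h(c)) when fits are given, the CDB table as CSV, and a machine-readable
#' `summary.json`.
#'
#' @param dataset a `speed_dataset` (or a `pse_table`).
#' @param fits named list of `speed_fit` objects (possibly empty).
#' @param out_dir output directory, created if needed.
#' @return invisibly, the vector of files written.
#' @export
render_report <- function(dataset, fits = list(), out_dir) {
  table <- if (inherits(dataset, "speed_dataset")) pse_summary(dataset) else dataset
  check_table(table)
  if (inherits(fits, "speed_fit")) fits <- list(fit = fits)
  if (length(fits) > 0 && is.null(names(fits))) {
    names(fits) <- paste0("fit", seq_along(fits))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  cdb <- compute_cdb(table)
  cdb_path <- file.path(out_dir, "cdb_table.csv")
  utils::write.csv(cdb, cdb_path, row.names = FALSE)
  files <- c(files, cdb_path)

  conds <- table[, c("condition_id", "v_ref", "c_ref", "c_test")]
  overlays <- NULL
  if (length(fits) > 0) {
    overlays <- do.call(rbind, lapply(names(fits), function(nm) {
      d <- predict_cdb(fits[[nm]]$observer, conds)
      d$model <- nm
      d
    }))
  }

  p <- ggplot2::ggplot(cdb, ggplot2::aes(x = .data$v_ref, y = .data$cdb)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$cdb - .data$sem, ymax = .data$cdb + .data$sem),
      width = 0.3) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~contrast_pair) +
    ggplot2::scale_x_log10(breaks = sort(unique(cdb$v_ref))) +
    ggplot2::labs(x = "reference speed (deg/s)",
                  y = expression(nu[HC] / nu[LC] ~ "at PSE (CDB)")) +
    ggplot2::theme_bw()
  if (!is.null(overlays)) {
    p <- p + ggplot2::geom_line(
      data = overlays,
      ggplot2::aes(x = .data$v_ref, y = .data$cdb, colour = .data$model,
                   group = .data$model))
  }
  cdb_fig <- file.path(out_dir, "cdb_by_speed.pdf")
  ggplot2::ggsave(cdb_fig, p, width = 8, height = 3.2)
  files <- c(files, cdb_fig)

  if (length(fits) > 0) {
    grid <- seq(0.5, 14, by = 0.1)
    cs <- seq(0.01, 1, by = 0.01)
    comp <- do.call(rbind, lapply(names(fits), function(nm) {
      ob <- fits[[nm]]$observer
      rbind(
        data.frame(model = nm, panel = "prior p(v)", x = grid,
                   y = reconstruct_prior(ob$prior, grid)),
        data.frame(model = nm, panel = "g(v)", x = ob$likelihood$knot_speeds,
                   y = ob$likelihood$knot_g),
        data.frame(model = nm, panel = "h(c)", x = cs,
                   y = contrast_gain(ob$likelihood$contrast, cs))
      )
    }))
    pc <- ggplot2::ggplot(comp, ggplot2::aes(x = .data$x, y = .data$y,
                                             colour = .data$model)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~panel, scales = "free") +
      ggplot2::labs(x = "speed (deg/s) / contrast (fraction)", y = NULL) +
      ggplot2::theme_bw()
    comp_fig <- file.path(out_dir, "model_components.pdf")
    ggplot2::ggsave(comp_fig, pc, width = 9, height = 3)
    files <- c(files, comp_fig)
  }

  summary_doc <- list(
    schema_version = "1.0",
    n_conditions = nrow(table),
    cdb = cdb,
    fits = lapply(fits, function(f) {
      list(variant = if (is.null(f$ratio)) "bayesian" else "combined",
           sse = f$sse, r2 = f$r2,
           prior_slopes = f$observer$prior$knot_slopes,
           likelihood_g = f$observer$likelihood$knot_g,
           q = f$observer$likelihood$contrast$q,
           c50 = f$observer$likelihood$contrast$c50)
    })
  )
  sum_path <- file.path(out_dir, "summary.json")
  writeLines(jsonlite::toJSON(summary_doc, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns"), sum_path)
  files <- c(files, sum_path)
  invisible(files)
}
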