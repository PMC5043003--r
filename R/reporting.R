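#' Cross-method concordance of significance flags
#'
#' Given per-method significance flags over a common set of endpoint
#' comparisons, counts significant calls per method and computes the
#' pairwise agreement matrix: the percentage of comparisons on which two
#' methods give the same significant/non-significant status. Agreement is
#' over binary status only (a shared "significant" and a shared
#' "not significant" both count as agreement).
#'
#' @param flags A data frame with key columns `endpoint`, `gender`, `time`,
#'   `comparison` and one logical column per method.
#' @param methods Character vector naming the flag columns; defaults to all
#'   logical columns.
#' @return A `concordance_summary` list: `E` (comparison universe size),
#'   `counts` (named significant counts), `agreement` (percent matrix) and
#'   `discordant` (tibble of comparisons on which any two methods differ).
#' @export
concordance <- function(flags, methods = NULL) {
  keys <- c("endpoint", "gender", "time", "comparison")
  missing <- setdiff(keys, names(flags))
  if (length(missing)) {
    stop("flag table lacks key column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(methods)) {
    methods <- names(flags)[vapply(flags, is.logical, logical(1))]
  }
  if (length(methods) < 1) stop("no method columns", call. = FALSE)
  if (anyNA(flags[methods])) {
    stop("missing flag values; all methods must cover the same comparisons",
         call. = FALSE)
  }
  E <- nrow(flags)
  counts <- vapply(methods, function(m) sum(flags[[m]]), numeric(1))
  agreement <- matrix(100, length(methods), length(methods),
                      dimnames = list(methods, methods))
  for (i in seq_along(methods)) {
    for (j in seq_along(methods)) {
      if (i < j) {
        agr <- 100 * mean(flags[[methods[i]]] == flags[[methods[j]]])
        agreement[i, j] <- agr
        agreement[j, i] <- agr
      }
    }
  }
  any_diff <- rowSums(!!sapply(methods, function(m) flags[[m]])) %in%
    seq_len(length(methods) - 1)
  discordant <- flags[any_diff, c(keys, methods), drop = FALSE]
  structure(
    list(E = E, counts = counts, agreement = agreement,
         discordant = tibble::as_tibble(discordant)),
    class = "concordance_summary"
  )
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("Concordance over", x$E, "endpoint comparisons\n")
  cat("significant counts:\n")
  print(x$counts)
  cat("pairwise agreement (%):\n")
  print(round(x$agreement, 1))
  cat(nrow(x$discordant), "discordant comparison(s)\n")
  invisible(x)
}

#' All-endpoints-at-a-glance SES panel plot
#'
#' Point estimates with 95% CI whiskers for every endpoint comparison, one
#' panel per gender and comparison, with a zero reference line and the
#' biological relevance limits at `-L` and `+L`; glyphs are coloured by the
#' case a--d classification. Endpoints appear in the order of the data (or
#' `endpoint_order`).
#'
#' @param ses_results Output of [ses_batch()].
#' @param limits Relevance limit `L`.
#' @param path Optional output file; written as SVG (vector, deterministic
#'   for fixed inputs).
#' @param endpoint_order Optional endpoint display order.
#' @param width,height Device size in inches when writing to `path`.
#' @return The ggplot object, invisibly.
#' @export
ses_panel_plot <- function(ses_results, limits = 1, path = NULL,
                           endpoint_order = NULL, width = 10, height = 12) {
  res <- ses_results[!ses_results$degenerate, , drop = FALSE]
  if (nrow(res) < 1) stop("no non-degenerate SES results", call. = FALSE)
  ord <- endpoint_order %||% rev(unique(res$endpoint))
  res$endpoint_f <- factor(res$endpoint, levels = ord)
  res$time_f <- factor(res$time, levels = sort(unique(res$time)))
  res$case <- factor(res$case, levels = c("a", "b", "c", "d"))
  p <- ggplot2::ggplot(
    res,
    ggplot2::aes(x = .data$d, y = .data$endpoint_f, colour = .data$case,
                 shape = .data$time_f)
  ) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = c(-limits, limits),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
      height = 0, linewidth = 0.4,
      position = ggplot2::position_dodge(width = 0.6)
    ) +
    ggplot2::geom_point(size = 1.2,
                        position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::facet_grid(gender ~ comparison) +
    ggplot2::scale_colour_manual(
      values = c(a = "grey40", b = "orange3", c = "red3", d = "steelblue"),
      drop = FALSE, name = "case"
    ) +
    ggplot2::labs(x = "standardized effect size (treatment - control, SD)",
                  y = NULL, shape = "month") +
    ggplot2::theme_bw(base_size = 8)
  if (!is.null(path)) {
    grDevices::svg(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    print(p)
  }
  invisible(p)
}

#' Run the full analysis pipeline on a synthetic or supplied trial
#'
#' Orchestrates the whole evaluation: simulate (or load) a trial, aggregate
#' to cage level, SES analysis of every comparison, decision-tree classical
#' analysis, the three fixed single-method analyses, AR(1) REML fits of the
#' longitudinal series per gender, cross-method concordance, the SES panel
#' figure, and CSV/JSON exports plus a manifest with parameter and output
#' hashes. Stage failures abort with the stage name; outputs written before
#' the failure are retained.
#'
#' @param out_dir Output directory (created if absent).
#' @param design A `trial_design`.
#' @param measurements Optional measurement table; when `NULL` a synthetic
#'   panel trial plus growth series are generated under `seed`.
#' @param growth_data Optional longitudinal table (body weight and feed).
#' @param seed Integer seed for the synthetic stages.
#' @param limits Relevance limit for the SES analysis.
#' @param alpha Significance level for the classical analyses.
#' @return A report bundle (list) with all result tables, the concordance
#'   summary, fitted longitudinal models and the manifest, invisibly.
#' @export
run_full_analysis <- function(out_dir, design = default_design(),
                              measurements = NULL, growth_data = NULL,
                              seed = 1, limits = 1, alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  stages <- character(0)

  measurements <- stage("simulate", {
    measurements %||% simulate_trial(design, seed = seed)
  })
  growth_data <- stage("simulate", {
    growth_data %||% simulate_growth(design, seed = seed)
  })
  stages <- c(stages, "simulate")

  cage <- stage("aggregate", cage_aggregate(measurements, design))
  write_table_csv(cage, file.path(out_dir, "cage_table.csv"))
  write_table_csv(group_summary(cage),
                  file.path(out_dir, "group_summary.csv"))
  stages <- c(stages, "aggregate")

  ses <- stage("ses", ses_batch(cage, design, limits = limits))
  write_table_csv(ses, file.path(out_dir, "ses_results.csv"))
  stages <- c(stages, "ses")

  classical <- stage("classical", decision_tree_batch(cage, design,
                                                      alpha = alpha))
  write_table_csv(classical, file.path(out_dir, "classical_results.csv"))
  stages <- c(stages, "classical")
  single <- stage("classical", {
    lapply(c("anova_t", "anova_dunnett", "kw_wilcoxon"), function(m) {
      run_single_method(cage, design, m, alpha = alpha)
    })
  })
  names(single) <- c("anova_t", "anova_dunnett", "kw_wilcoxon")
  for (m in names(single)) {
    write_table_csv(single[[m]],
                    file.path(out_dir, paste0("method_", m, ".csv")))
  }
  stages <- c(stages, "single_methods")

  fits <- stage("longitudinal", {
    lapply(stats::setNames(design$genders, design$genders), function(g) {
      bw <- growth_data[growth_data$endpoint == "body_weight" &
                          growth_data$gender == g, , drop = FALSE]
      bw_cage <- cage_aggregate(bw, design)
      fit_gls_ar1(bw_cage, design$control, response = "value",
                  time_col = "time")
    })
  })
  long_summary <- dplyr::bind_rows(lapply(names(fits), function(g) {
    tibble::tibble(gender = g, rho = fits[[g]]$rho,
                   sigma = sqrt(fits[[g]]$sigma2), fits[[g]]$contrasts)
  }))
  write_table_csv(long_summary, file.path(out_dir, "longitudinal.csv"))
  stages <- c(stages, "longitudinal")

  conc <- stage("concordance", {
    keys <- c("endpoint", "gender", "time", "comparison")
    flags <- ses[!ses$degenerate, c(keys, "significant")]
    names(flags)[5] <- "ses"
    flags <- dplyr::inner_join(
      flags,
      stats::setNames(classical[, c(keys, "significant")],
                      c(keys, "decision_tree")),
      by = keys
    )
    for (m in names(single)) {
      flags <- dplyr::inner_join(
        flags,
        stats::setNames(single[[m]][, c(keys, "significant")],
                        c(keys, m)),
        by = keys
      )
    }
    concordance(flags)
  })
  jsonlite::write_json(
    list(E = conc$E, counts = as.list(conc$counts),
         agreement = as.data.frame(conc$agreement)),
    file.path(out_dir, "concordance.json"), auto_unbox = TRUE, digits = NA
  )
  stages <- c(stages, "concordance")

  stage("plots", {
    ses_panel_plot(ses, limits = limits,
                   path = file.path(out_dir, "ses_panel.svg"))
  })
  stages <- c(stages, "plots")

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    package = "cagetrial",
    version = as.character(utils::packageVersion("cagetrial")),
    seed = seed, limits = limits, alpha = alpha,
    design = unclass(design),
    stages = stages,
    n_comparisons = conc$E,
    file_md5 = as.list(tools::md5sum(sort(outputs)))
  )
  names(manifest$file_md5) <- basename(names(manifest$file_md5))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(measurements = measurements, cage = cage, ses = ses,
                 classical = classical, single = single, fits = fits,
                 concordance = conc, manifest = manifest))
}
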