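# Serialization of results: single-strain score JSON, and the full
# analysis bundle as JSON plus per-table TSVs.

#' Write an adaptation result to JSON
#'
#' @param result an `adaptation_result`.
#' @param path output path.
#' @export
write_result_json <- function(result, path) {
  stopifnot(inherits(result, "adaptation_result"))
  jsonlite::write_json(
    list(strain = result$strain, C = result$C, P = result$P,
         score = result$score,
         target = result$target, target_optimum = result$target_optimum,
         fully_used_genes = result$fully_used_genes,
         alpha = as.list(result$alpha_values),
         status = result$solver_status,
         objective_bound = result$objective_bound),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a full analysis bundle
#'
#' Emits `bundle.json` plus `keygenes.tsv`, `conditional_scores.tsv`,
#' `correlations.tsv` and `venn.json` into a directory.
#'
#' @param report an `mri_report` from [run_full_analysis()].
#' @param dir output directory (created if missing).
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "mri_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scores <- data.frame(
    strain = names(report$unconditional),
    P = vapply(report$unconditional, `[[`, 0L, "P"),
    score = vapply(report$unconditional, `[[`, 0L, "score"))
  utils::write.table(scores, file.path(dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(report$key_genes),
                     file.path(dir, "keygenes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(report$conditional)) {
    cond <- do.call(rbind, lapply(names(report$conditional), function(g) {
      data.frame(target = g,
                 strain = names(report$conditional[[g]]),
                 score = vapply(report$conditional[[g]], `[[`, 0L, "score"),
                 target_optimum = vapply(report$conditional[[g]], `[[`, 0,
                                         "target_optimum"))
    }))
    utils::write.table(cond, file.path(dir, "conditional_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (is.list(report$correlations)) {
    corr <- do.call(rbind, lapply(names(report$correlations), function(k) {
      r <- report$correlations[[k]]
      data.frame(pair = k, quantity = r$quantity, n = r$n,
                 pearson_r = r$pearson_r, p_value = r$p_value)
    }))
    utils::write.table(corr, file.path(dir, "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$usage_comparison) &&
      !is.matrix(report$usage_comparison))
    jsonlite::write_json(as.list(report$usage_comparison),
                         file.path(dir, "venn.json"), auto_unbox = TRUE,
                         digits = NA)
  bundle <- list(
    C = report$C,
    wt_strain = report$wt_strain,
    medium = list(unlimited = report$medium$unlimited,
                  carbon_source = report$medium$carbon_source),
    scores = stats::setNames(as.list(scores$score), scores$strain),
    wt_full_usage_set = report$wt_full_usage_set,
    key_genes = report$key_genes$gene[report$key_genes$selected],
    score_ratios = as.list(report$score_ratios),
    correlations_computed = is.list(report$correlations))
  jsonlite::write_json(bundle, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
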