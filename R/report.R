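#' Render a Markdown report for a pipeline run
#'
#' Summarizes a completed run directory: trial-selection counts, group beta
#' and variance-explained topographies (as figure-data tables), residual
#' cluster statistics with the minimum-duration sensor mask, and the
#' hemispheric lateralization contrasts. Each figure has a deterministic
#' TSV with its underlying data written next to the report.
#'
#' @param runDir directory produced by [runPipeline()]
#' @return path of the written \code{report.md}, invisibly
#' @export
makeReport <- function(runDir) {
  need <- c("participants.tsv", "betas.tsv", "clusters.tsv",
            "duration_mask.tsv", "hemisphere_tests.json", "layout.json")
  miss <- need[!file.exists(file.path(runDir, need))]
  if (length(miss))
    stop("run directory incomplete; missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rd <- function(f) utils::read.table(file.path(runDir, f), header = TRUE,
                                      sep = "\t", stringsAsFactors = FALSE)
  counts <- rd("participants.tsv")
  betas <- rd("betas.tsv")
  clusters <- rd("clusters.tsv")
  dmask <- rd("duration_mask.tsv")
  ht <- jsonlite::read_json(file.path(runDir, "hemisphere_tests.json"),
                            simplifyVector = TRUE)
  num <- function(x) suppressWarnings(as.numeric(x))  # JSON Inf round-trip
  layout <- readLayoutJson(file.path(runDir, "layout.json"))

  topo <- stats::aggregate(
    betas[, c("beta_saccade", "beta_stimulus", "r2")],
    by = list(site = betas$site), FUN = mean)
  topo <- merge(layout@sites, topo, by = "site")
  utils::write.table(topo, file.path(runDir, "fig_topographies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sig <- clusters[clusters$p <= 0.05, , drop = FALSE]
  lines <- c(
    "# Pre-saccadic residual gradient analysis report", "",
    sprintf("Participants: %d. Mean saccade trials kept: %.1f; mean fixation trials kept: %.1f; mean detection rate: %.3f.",
            nrow(counts), mean(counts$n_sacc_kept), mean(counts$n_fix_kept),
            mean(counts$detection_rate)), "",
    "## Condition-template GLM topographies",
    "Group-mean beta coefficients and variance explained per site: `fig_topographies.tsv`.",
    sprintf("Median R^2 across sites: %.3f.", stats::median(topo$r2)), "",
    "## Residual cluster statistics", "")
  if (nrow(sig) == 0L) {
    lines <- c(lines, "No significant spatiotemporal clusters: the residual planar gradients do not deviate reliably from zero at alpha = 0.05.")
  } else {
    lines <- c(lines,
               sprintf("%d significant cluster(s) (alpha = 0.05):", nrow(sig)),
               "", "| cluster | sign | mass | points | p |",
               "|---|---|---|---|---|",
               sprintf("| %d | %+d | %.1f | %d | %.4g |", sig$cluster,
                       sig$sign, sig$mass, sig$n_points, sig$p))
  }
  lines <- c(lines, "",
             sprintf("Sensors significant for at least 12.5 ms: %d of %d (`duration_mask.tsv`).",
                     sum(dmask$duration_mask), nrow(dmask)), "",
             "## Lateralization", "",
             sprintf("Variance explained, left minus right hemisphere: t(%d) = %.2f, p = %.3g.",
                     ht$hemisphereTests$r2$df, num(ht$hemisphereTests$r2$t),
                     num(ht$hemisphereTests$r2$p)),
             sprintf("Stimulus beta lateralization: t(%d) = %.2f, p = %.3g.",
                     ht$hemisphereTests$betaStimulus$df,
                     num(ht$hemisphereTests$betaStimulus$t),
                     num(ht$hemisphereTests$betaStimulus$p)), "")
  pt <- ht$proportionTests
  for (w in names(pt))
    lines <- c(lines,
               sprintf("Significant-sensor counts by hemisphere (%s window): X^2(1) = %.2f, adjusted p = %.3g, BF = %.2f.",
                       w, num(pt[[w]]$chi2$statistic),
                       num(pt[[w]]$chi2$pAdjusted), num(pt[[w]]$bf)))
  lines <- c(lines, "",
             "Per-participant left-minus-right residual traces: `lateralization.tsv`; median residual traces: `median_residuals.tsv`.")
  out <- file.path(runDir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
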