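#' Published screening effects used to parameterize the simulator
#'
#' The top-5 up-regulated and top-5 down-regulated plasma miRNAs reported
#' for each case-vs-control comparison of the myocardial-infarction
#' cohort study this package reanalyses, with their linear fold changes
#' (case-group mean over NHF control mean; values below 1 are
#' down-regulated). These printed values are treated as ground truth by
#' the synthetic-cohort generator: a planted miRNA's expected case-group
#' mean is `baseline * fold_change`.
#'
#' miR-320 and miR-204 are down-regulated in every comparison, which is
#' the study's central screening finding.
#'
#' @param comparison Optional case-group label (`"AMNHF"`, `"OMHF"` or
#'   `"AMHF"`) to restrict the table to a single comparison; by default
#'   all three comparisons are returned.
#' @return `data.frame` with columns `mirna`, `control`, `case`,
#'   `fold_change`, `p_value` and `direction`.
#' @examples
#' head(plantedFoldChanges("AMNHF"))
#' @export
plantedFoldChanges <- function(comparison = c("AMNHF", "OMHF", "AMHF")) {
  comparison <- match.arg(comparison, several.ok = TRUE)
  row <- function(case, mirna, fc, p, dir)
    data.frame(mirna = mirna, control = "NHF", case = case,
               fold_change = fc, p_value = p, direction = dir,
               stringsAsFactors = FALSE)
  tab <- rbind(
    # NHF vs AMNHF
    row("AMNHF", "hsa-miR-409-3p",  6.653, 0.013, "up"),
    row("AMNHF", "hsa-miR-26b-5p",  5.765, 0.032, "up"),
    row("AMNHF", "hsa-miR-369-3p",  5.543, 0.035, "up"),
    row("AMNHF", "hsa-miR-148b-3p", 4.432, 0.041, "up"),
    row("AMNHF", "hsa-miR-329",     4.132, 0.047, "up"),
    row("AMNHF", "hsa-miR-320",     0.765, 0.001, "down"),
    row("AMNHF", "hsa-miR-204",     0.643, 0.005, "down"),
    row("AMNHF", "hsa-miR-20b-3p",  0.543, 0.014, "down"),
    row("AMNHF", "hsa-miR-767-5p",  0.532, 0.018, "down"),
    row("AMNHF", "hsa-miR-299-5p",  0.412, 0.023, "down"),
    # NHF vs OMHF
    row("OMHF", "hsa-miR-3941",    6.753, 0.015, "up"),
    row("OMHF", "hsa-miR-338-5p",  5.755, 0.034, "up"),
    row("OMHF", "hsa-miR-433",     4.546, 0.041, "up"),
    row("OMHF", "hsa-miR-19a-3p",  4.432, 0.045, "up"),
    row("OMHF", "hsa-miR-329",     4.165, 0.049, "up"),
    row("OMHF", "hsa-miR-320",     0.865, 0.003, "down"),
    row("OMHF", "hsa-miR-204",     0.748, 0.007, "down"),
    row("OMHF", "hsa-miR-2110",    0.663, 0.015, "down"),
    row("OMHF", "hsa-miR-1247-5p", 0.542, 0.019, "down"),
    row("OMHF", "hsa-miR-296-5p",  0.432, 0.025, "down"),
    # NHF vs AMHF
    row("AMHF", "hsa-miR-3667-5p", 8.753, 0.009, "up"),
    row("AMHF", "hsa-miR-4275",    7.751, 0.013, "up"),
    row("AMHF", "hsa-miR-647",     7.548, 0.019, "up"),
    row("AMHF", "hsa-miR-1284",    6.433, 0.023, "up"),
    row("AMHF", "hsa-miR-1306-3p", 6.165, 0.024, "up"),
    row("AMHF", "hsa-miR-320",     0.785, 0.007, "down"),
    row("AMHF", "hsa-miR-204",     0.758, 0.009, "down"),
    row("AMHF", "hsa-miR-205-5p",  0.675, 0.012, "down"),
    row("AMHF", "hsa-miR-423-5p",  0.641, 0.013, "down"),
    row("AMHF", "hsa-miR-21-3p",   0.572, 0.021, "down")
  )
  tab[tab$case %in% comparison, , drop = FALSE]
}
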