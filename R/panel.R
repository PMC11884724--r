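#' Reference sweet sorghum SSR panel tables
#'
#' Published per-marker summaries for a 13-marker SSR panel genotyped on 91
#' sweet sorghum accessions from 5 Ethiopian collection zones, bundled as
#' plain-text reference inputs:
#'
#' * `"markers"` — marker metadata (repeat motif, chromosome, primer pair,
#'   annealing temperature);
#' * `"locus_stats"` — pooled-sample per-marker diversity (major allele
#'   frequency, sample size, allele number, PIC, observed heterozygosity,
#'   gene diversity);
#' * `"fstats"` — per-marker F-statistics over the 5 zones (Ht, mean He,
#'   mean Ho, Fis, Fit, Fst, Nm).
#'
#' These tables serve as worked-example input for the consistency checks the
#' package ships (column means, the definitional identities among
#' F-statistics, PIC grading).
#'
#' @param table Which table to load.
#' @return A tibble.
#' @examples
#' fs <- ssr_panel("fstats")
#' mean(fs$fst)
#' @export
ssr_panel <- function(table = c("locus_stats", "fstats", "markers")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0("ssr_panel_", table, ".tsv"),
                      package = "ssrpop", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
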