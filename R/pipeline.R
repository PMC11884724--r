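#' Run the full SSR diversity and structure analysis
#'
#' One call from a genotype table to the complete report bundle: per-locus
#' diversity, per-population allelic patterns, F-statistics and gene flow,
#' pairwise Fst / Nei distance / Nm, AMOVA with permutation test, PCoA, a
#' UPGMA tree in Newick form, an admixture run grid with Evanno delta-K, and
#' a machine-readable JSON summary of the headline numbers. Stages that need
#' two or more populations (F-statistics, AMOVA, pairwise distances) are
#' skipped with a notice on single-population input.
#'
#' All randomness flows from `seed`: the AMOVA permutation stream and each
#' admixture run receive sub-seeds derived from it, so re-running an
#' identical configuration reproduces every output.
#'
#' @param g An [ssr_genotypes] table (e.g. from [read_genotypes()] or
#'   [simulate_ssr()]).
#' @param out_dir Output directory, created if absent.
#' @param binning Optional [binning_spec()] applied first.
#' @param amova_perm AMOVA permutations (default 999).
#' @param k_range Admixture grid of cluster numbers (default `1:8`).
#' @param runs_per_k Replicate runs per `k` (default 8).
#' @param burnin,reps Admixture chain lengths per run.
#' @param tree_distance `"shared_allele"` or `"nei"`-style squared genotypic
#'   distance for the individual tree.
#' @param seed Root seed.
#' @return Invisibly, a list with every fitted object plus `summary` (the
#'   headline values) and `files` (paths written).
#' @export
run_pipeline <- function(g, out_dir, binning = NULL,
                         amova_perm = 999, k_range = 1:8, runs_per_k = 8,
                         burnin = 30000, reps = 15000,
                         tree_distance = c("shared_allele", "squared"),
                         seed = 1L) {
  stopifnot(inherits(g, "ssr_genotypes"), length(k_range) >= 1)
  tree_distance <- match.arg(tree_distance)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_lines <- c(
    sprintf("ssrpop %s pipeline, %s", as.character(utils::packageVersion("ssrpop")),
            format(t0, "%Y-%m-%d %H:%M:%S")),
    sprintf("input: %d individuals x %d loci, %d populations; root seed %d",
            n_individuals(g), n_loci(g), length(unique(pop_table(g)$pop)), seed)
  )
  files <- character(0)
  emit <- function(tb, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(tb, path, progress = FALSE)
    files[[name]] <<- path
  }
  if (!is.null(binning)) g <- bin_alleles(g, binning)
  multi_pop <- length(unique(pop_table(g)$pop)) >= 2

  ls_tb <- locus_summary(g)
  emit(add_summary_rows(ls_tb), "locus_summary.csv")
  patt <- allelic_patterns(g)
  emit(add_summary_rows(patt), "allelic_patterns.csv")

  fs <- NULL
  pw_fst <- nei <- nm <- NULL
  if (multi_pop) {
    fs <- per_locus_fstats(g)
    emit(add_summary_rows(fs), "fstats.csv")
    pw_fst <- pairwise_fst(g)
    nei <- nei_distance(g)
    nm <- gene_flow(pw_fst)
    # printed-table layout: Fst below the diagonal, Nei distance above
    comb <- unclass(pw_fst)
    comb[upper.tri(comb)] <- unclass(nei)[upper.tri(nei)]
    emit(as_tibble(as.data.frame(comb), rownames = "pop"),
         "pairwise_fst_nei.csv")
    emit(as_tibble(as.data.frame(unclass(nm)), rownames = "pop"),
         "pairwise_nm.csv")
  } else {
    log_lines <- c(log_lines, "single population: F-statistics, pairwise distances and AMOVA skipped")
  }

  am <- NULL
  sqd <- individual_squared_distances(g)
  if (multi_pop) {
    am <- run_amova(sqd, pop_table(g), n_perm = amova_perm,
                    seed = seed + 1000L)
    emit(tidy(am), "amova.csv")
  }

  ord <- pcoa(sqd)
  emit(ord$coordinates, "pcoa_coordinates.csv")
  emit(tibble(axis = seq_along(ord$percent), percent = ord$percent,
              cumulative = ord$cumulative_percent), "pcoa_axes.csv")

  tree_d <- if (tree_distance == "shared_allele") shared_allele_distance(g) else sqd
  tr <- upgma(tree_d)
  write_newick(tr, file.path(out_dir, "upgma.nwk"))
  files[["upgma.nwk"]] <- file.path(out_dir, "upgma.nwk")

  runs <- list()
  for (k in k_range) {
    for (r in seq_len(runs_per_k)) {
      runs[[length(runs) + 1]] <- run_admixture(
        g, k = k, burnin = burnin, reps = reps,
        seed = seed + 10000L + 100L * k + r
      )
    }
  }
  ev <- NULL
  if (length(unique(k_range)) >= 3 && runs_per_k >= 2) {
    ev <- evanno(runs)
    emit(ev$table, "evanno.csv")
  }
  best <- if (!is.null(ev) && !is.na(ev$selected_k)) ev$selected_k else max(k_range)
  best_runs <- align_labels(Filter(function(r) r$k == best, runs))
  emit(best_runs[[1]]$Q, "admixture_q.csv")

  smry <- list(
    n_individuals = n_individuals(g),
    n_loci = n_loci(g),
    total_alleles = sum(ls_tb$n_alleles),
    mean_maf = mean(ls_tb$maf),
    mean_pic = mean(ls_tb$pic),
    mean_ho = mean(ls_tb$ho),
    mean_ht = if (!is.null(fs)) mean(fs$ht) else NA,
    mean_fis = if (!is.null(fs)) mean(fs$fis, na.rm = TRUE) else NA,
    mean_fit = if (!is.null(fs)) mean(fs$fit, na.rm = TRUE) else NA,
    mean_fst = if (!is.null(fs)) mean(fs$fst, na.rm = TRUE) else NA,
    mean_nm = if (!is.null(fs)) mean(fs$nm[is.finite(fs$nm)]) else NA,
    amova_percent_among = if (!is.null(am)) am$table$percent[1] else NA,
    amova_percent_within = if (!is.null(am)) am$table$percent[2] else NA,
    amova_p = if (!is.null(am)) am$p_value else NA,
    pcoa_first3_percent = ord$cumulative_percent[min(3, length(ord$percent))],
    selected_k = if (!is.null(ev)) ev$selected_k else NA,
    seed = seed
  )
  jsonlite::write_json(smry, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files[["summary.json"]] <- file.path(out_dir, "summary.json")
  log_lines <- c(log_lines, sprintf(
    "done in %.1f s; %d files in %s",
    as.numeric(difftime(Sys.time(), t0, units = "secs")), length(files), out_dir
  ))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  message(paste(log_lines, collapse = "\n"))
  invisible(list(
    genotypes = g, locus_summary = ls_tb, allelic_patterns = patt,
    fstats = fs, pairwise_fst = pw_fst, nei = nei, nm = nm, amova = am,
    pcoa = ord, upgma = tr, admixture_runs = runs, evanno = ev,
    summary = smry, files = files
  ))
}
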