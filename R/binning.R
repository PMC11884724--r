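#' Binning rule for raw fragment sizes
#'
#' Gel-scored fragment sizes rarely fall exactly on the repeat ladder; a
#' binning rule collapses near-identical sizes into discrete allele classes
#' before any frequency is computed.
#'
#' * `"exact"` — identity, sizes are already discrete allele classes.
#' * `"cluster"` — single-linkage clustering of the distinct sizes observed at
#'   a locus, cutting every link longer than `tolerance` bp; each bin is
#'   relabelled by its rounded mean size (round-half-to-even, so binning is
#'   platform-stable).
#' * `"ladder"` — snap each size onto the arithmetic ladder
#'   `offset + repeat_length * round((size - offset) / repeat_length)`.
#'
#' @param mode One of `"exact"`, `"cluster"`, `"ladder"`.
#' @param tolerance Non-negative single-linkage cut distance in bp
#'   (`"cluster"` mode).
#' @param offset,repeat_length Ladder origin and rung spacing in bp
#'   (`"ladder"` mode); `repeat_length >= 1`.
#' @return A `binning_spec` list.
#' @export
binning_spec <- function(mode = c("exact", "cluster", "ladder"),
                         tolerance = 0, offset = 0, repeat_length = 2) {
  mode <- match.arg(mode)
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  if (mode == "ladder" && repeat_length < 1) {
    stop("repeat_length must be >= 1", call. = FALSE)
  }
  structure(list(mode = mode, tolerance = tolerance, offset = offset,
                 repeat_length = repeat_length),
            class = "binning_spec")
}

#' Collapse raw allele sizes into allele classes
#'
#' Applies a [binning_spec()] locus by locus. The number of distinct alleles
#' per locus never increases, and `tolerance = 0` clustering equals
#' `mode = "exact"`.
#'
#' @param g An [ssr_genotypes] table with numeric allele sizes.
#' @param spec A [binning_spec()].
#' @return An [ssr_genotypes] table with binned allele labels.
#' @export
bin_alleles <- function(g, spec = binning_spec()) {
  stopifnot(inherits(g, "ssr_genotypes"), inherits(spec, "binning_spec"))
  if (spec$mode == "exact") return(g)
  tb <- as_tibble(g)
  if (spec$mode == "ladder") {
    snap <- function(x) spec$offset +
      spec$repeat_length * round((x - spec$offset) / spec$repeat_length)
    tb$a1 <- snap(tb$a1)
    tb$a2 <- snap(tb$a2)
  } else {
    for (loc in attr(g, "loci")) {
      sel <- tb$locus == loc
      sizes <- sort(unique(c(tb$a1[sel], tb$a2[sel])))
      sizes <- sizes[!is.na(sizes)]
      if (length(sizes) < 2) next
      # single linkage in 1-D: cut sorted gaps wider than the tolerance
      bin <- cumsum(c(0, diff(sizes) > spec$tolerance))
      rep_size <- round(tapply(sizes, bin, mean))[as.character(bin)]
      map <- setNames(as.numeric(rep_size), sizes)
      tb$a1[sel] <- unname(map[as.character(tb$a1[sel])])
      tb$a2[sel] <- unname(map[as.character(tb$a2[sel])])
    }
  }
  ssr_genotypes(tb, individuals = attr(g, "individuals"), loci = attr(g, "loci"))
}
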