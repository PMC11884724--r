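#' Read a codominant SSR genotype file
#'
#' Two plain-text dialects are supported.
#'
#' * `"genalex"` — the GenAlEx codominant CSV layout: a first row with the
#'   locus count, sample count, population count and population sizes; a second
#'   row with a dataset title and the population names; a third row with
#'   `Ind, Pop` followed by one locus name per pair of allele columns; then one
#'   row per individual with two allele-size columns per locus.
#' * `"long"` — one row per (individual, locus) call:
#'   `id, pop, locus, a1[, a2]`. A row with a single allele column is read as
#'   a homozygote (single gel band).
#'
#' @param path File to read (CSV).
#' @param dialect `"genalex"` or `"long"`.
#' @param missing Code standing for a missing allele (default `"0"`).
#' @return An [ssr_genotypes] table.
#' @export
read_genotypes <- function(path, dialect = c("genalex", "long"), missing = "0") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "long") {
    tb <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    if (!all(c("id", "pop", "locus", "a1") %in% names(tb))) {
      stop("long-table needs columns id, pop, locus, a1[, a2]", call. = FALSE)
    }
    if (!"a2" %in% names(tb)) tb$a2 <- tb$a1
    tb$a2[is.na(tb$a2)] <- tb$a1[is.na(tb$a2)]
    bad <- is.na(tb$id) | is.na(tb$locus) | is.na(tb$a1)
    if (any(bad)) {
      stop("malformed long-table row(s): ", paste(which(bad), collapse = ", "),
           call. = FALSE)
    }
    a1 <- decode_allele(tb$a1, missing, path)
    a2 <- decode_allele(tb$a2, missing, path)
    a2[is.na(a1)] <- NA  # a whole call is missing, never half of it
    a1[is.na(a2)] <- NA
    return(ssr_genotypes(tibble(
      id = tb$id, pop = tb$pop, locus = tb$locus, a1 = a1, a2 = a2
    )))
  }
  raw <- readr::read_csv(path, col_names = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) < 4) stop("not a GenAlEx codominant file: ", path, call. = FALSE)
  n_loci <- as.integer(raw[[1]][1])
  n_ind <- as.integer(raw[[2]][1])
  n_pop <- as.integer(raw[[3]][1])
  if (anyNA(c(n_loci, n_ind, n_pop))) {
    stop("malformed GenAlEx header row 1 in ", path, call. = FALSE)
  }
  header <- unname(unlist(raw[3, ]))
  locus_names <- header[seq(3, by = 2, length.out = n_loci)]
  if (anyNA(locus_names) || anyDuplicated(locus_names)) {
    stop("locus names in header row 3 are missing or duplicated", call. = FALSE)
  }
  body <- raw[seq(4, length.out = n_ind), , drop = FALSE]
  if (nrow(body) < n_ind || anyNA(body[[1]])) {
    stop("GenAlEx body has fewer individual rows than the header declares",
         call. = FALSE)
  }
  long <- purrr::map_dfr(seq_len(n_loci), function(j) {
    tibble(
      id = as.character(body[[1]]),
      pop = as.character(body[[2]]),
      locus = locus_names[j],
      a1 = decode_allele(body[[2 * j + 1]], missing, path),
      a2 = decode_allele(body[[2 * j + 2]], missing, path)
    )
  })
  half <- xor(is.na(long$a1), is.na(long$a2))
  if (any(half)) {
    # one scored band next to a missing slot: homozygote by convention
    long$a1[half] <- dplyr::coalesce(long$a1[half], long$a2[half])
    long$a2[half] <- long$a1[half]
  }
  g <- ssr_genotypes(long, individuals = as.character(body[[1]]),
                     loci = locus_names)
  empty <- vapply(split(is.na(g$a1), g$locus), all, logical(1))
  if (any(empty)) {
    warning("locus with no genotyped individuals retained: ",
            paste(names(empty)[empty], collapse = ", "), call. = FALSE)
  }
  g
}

decode_allele <- function(x, missing, path) {
  x <- as.character(x)
  x[!is.na(x) & x == missing] <- NA
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("non-numeric allele size(s) in ", path, ": ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Write a codominant SSR genotype file
#'
#' Inverse of [read_genotypes()]: `read_genotypes(write_genotypes(g, f), d)`
#' reproduces `g` for both dialects.
#'
#' @param g An [ssr_genotypes] table.
#' @param path Output CSV path.
#' @inheritParams read_genotypes
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, dialect = c("genalex", "long"),
                            missing = "0") {
  dialect <- match.arg(dialect)
  fmt <- function(x) {
    out <- ifelse(is.na(x), missing,
                  format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE))
    out
  }
  if (dialect == "long") {
    tb <- as_tibble(g)
    readr::write_csv(
      tibble(id = tb$id, pop = tb$pop, locus = tb$locus,
             a1 = fmt(tb$a1), a2 = fmt(tb$a2)),
      path, progress = FALSE
    )
    return(invisible(path))
  }
  ids <- attr(g, "individuals")
  loci <- attr(g, "loci")
  pops <- pop_table(g)
  sizes <- table(factor(pops$pop, levels = unique(pops$pop)))
  ncol_out <- 2 + 2 * length(loci)
  pad <- function(v) c(v, rep("", max(0, ncol_out - length(v))))
  l1 <- pad(c(length(loci), length(ids), length(sizes), as.integer(sizes)))
  l2 <- pad(c("ssrpop export", "", names(sizes)))
  l3 <- pad(c("Ind", "Pop", as.vector(rbind(loci, ""))))
  wide <- matrix("", nrow = length(ids), ncol = ncol_out)
  wide[, 1] <- ids
  wide[, 2] <- pops$pop
  for (j in seq_along(loci)) {
    sub <- g[g$locus == loci[j], ]
    sub <- sub[match(ids, sub$id), ]
    wide[, 2 * j + 1] <- fmt(sub$a1)
    wide[, 2 * j + 2] <- fmt(sub$a2)
  }
  out <- rbind(l1, l2, l3, wide)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(out, 1, paste, collapse = ","), con)
  invisible(path)
}
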