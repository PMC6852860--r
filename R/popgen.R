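#' Tally genotype calls for a biallelic marker
#'
#' Counts the three ordered genotype classes (first-allele homozygote,
#' heterozygote, second-allele homozygote) in a vector of genotype calls.
#' Calls are two-letter strings; heterozygotes are recognised irrespective of
#' the written allele order, so `"CT"` and `"TC"` fall in the same class.
#'
#' @param calls Character vector of genotype calls, e.g. `c("CC","CT","TT")`.
#'   `NA` entries are not allowed.
#' @param alleles Ordered pair of allele symbols, e.g. `c("C","T")`.
#' @param marker Marker name used in error messages and carried in the result.
#' @return An object of class `genotype_counts`: a list with elements
#'   `marker`, `alleles`, `counts` (length-3 named integer vector
#'   `hom_first`, `het`, `hom_second`) and `n`.
#' @examples
#' count_genotypes(c("CC", "CT", "TT", "TT"), c("C", "T"))
#' @export
count_genotypes <- function(calls, alleles, marker = "marker") {
  stopifnot(is.character(calls), length(calls) >= 1L,
            is.character(alleles), length(alleles) == 2L,
            alleles[1] != alleles[2])
  if (anyNA(calls)) {
    stop("missing genotype call for marker '", marker, "' (animal index ",
         paste(which(is.na(calls)), collapse = ", "), ")")
  }
  norm <- normalize_genotype(calls)
  g1 <- paste0(alleles[1], alleles[1])
  g2 <- paste0(alleles[2], alleles[2])
  ghet <- normalize_genotype(paste0(alleles[1], alleles[2]))
  known <- c(g1, ghet, g2)
  bad <- which(!norm %in% normalize_genotype(known))
  if (length(bad)) {
    stop("unknown allele symbol in call '", calls[bad[1]], "' for marker '",
         marker, "' (animal index ", bad[1], ")")
  }
  counts <- c(
    hom_first  = sum(norm == normalize_genotype(g1)),
    het        = sum(norm == ghet),
    hom_second = sum(norm == normalize_genotype(g2))
  )
  structure(
    list(marker = marker, alleles = alleles, counts = counts,
         n = sum(counts)),
    class = "genotype_counts"
  )
}

#' @rdname count_genotypes
#' @param hom_first,het,hom_second Nonnegative integer class counts, for
#'   building a `genotype_counts` object directly from a published table.
#' @export
genotype_counts <- function(hom_first, het, hom_second, alleles,
                            marker = "marker") {
  counts <- c(hom_first = as.integer(hom_first), het = as.integer(het),
              hom_second = as.integer(hom_second))
  stopifnot(all(counts >= 0L), sum(counts) >= 1L, length(alleles) == 2L)
  structure(
    list(marker = marker, alleles = alleles, counts = counts,
         n = sum(counts)),
    class = "genotype_counts"
  )
}

# sort the letters of each genotype string so "TC" == "CT"
normalize_genotype <- function(g) {
  vapply(strsplit(g, ""), function(x) paste(sort(x), collapse = ""), "")
}

#' Allele frequencies from genotype counts
#'
#' For a biallelic marker, the frequency of the first allele is
#' `(2 * hom_first + het) / (2n)` by direct gene counting.
#'
#' @param counts A `genotype_counts` object.
#' @return Named numeric vector of allele frequencies (sums to 1).
#' @examples
#' allele_frequencies(genotype_counts(43, 45, 208, c("C", "T")))
#' @export
allele_frequencies <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  if (counts$n == 0L) stop("empty cohort: no genotype calls for marker '",
                           counts$marker, "'")
  p <- (2 * counts$counts[["hom_first"]] + counts$counts[["het"]]) /
    (2 * counts$n)
  stats::setNames(c(p, 1 - p), counts$alleles)
}

#' Diversity indices from allele frequencies
#'
#' Computes, from a frequency vector `p`, expected homozygosity
#' `Ho = sum(p^2)`, expected heterozygosity `He = 1 - Ho`, the effective
#' allele number `Ne = 1 / Ho`, and the polymorphism information content
#' `PIC = He - sum_{i<j} 2 p_i^2 p_j^2` (Botstein's marker-informativeness
#' index), plus the minor allele frequency. The formulas are generic in the
#' number of alleles.
#'
#' @param freqs Numeric vector of allele frequencies summing to 1
#'   (within 1e-8).
#' @return A list with elements `Ho`, `He`, `Ne`, `PIC`, `MAF`.
#' @examples
#' diversity_indices(c(0.22, 0.78))
#' @export
diversity_indices <- function(freqs) {
  stopifnot(is.numeric(freqs), length(freqs) >= 2L,
            all(freqs >= 0), all(freqs <= 1))
  if (abs(sum(freqs) - 1) > 1e-8) stop("allele frequencies must sum to 1")
  ho <- sum(freqs^2)
  cross <- outer(freqs^2, freqs^2)
  pic <- 1 - ho - sum(cross[upper.tri(cross)] * 2)
  list(Ho = ho, He = 1 - ho, Ne = 1 / ho, PIC = pic, MAF = min(freqs))
}

#' Pearson chi-square test of Hardy-Weinberg equilibrium
#'
#' Compares observed genotype counts with the counts expected under
#' Hardy-Weinberg proportions `n * (p^2, 2pq, q^2)` computed from the exact
#' count-derived allele frequencies, on 1 degree of freedom (3 genotype
#' classes minus 2 estimated alleles). No continuity correction is applied.
#' A class with zero observed count still contributes `(0 - E)^2 / E`.
#'
#' @param counts A `genotype_counts` object; the marker must be polymorphic.
#' @return A list with elements `chi2`, `df`, `p_value` and
#'   `expected_counts` (which sum to `n`).
#' @examples
#' hwe_test(genotype_counts(43, 45, 208, c("C", "T")))
#' @export
hwe_test <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  p <- allele_frequencies(counts)[1]
  if (p == 0 || p == 1) {
    stop("marker '", counts$marker,
         "' is monomorphic: Hardy-Weinberg test undefined")
  }
  q <- 1 - p
  expected <- counts$n * c(hom_first = p^2, het = 2 * p * q, hom_second = q^2)
  chi2 <- sum((counts$counts - expected)^2 / expected)
  list(chi2 = unname(chi2), df = 1L,
       p_value = stats::pchisq(unname(chi2), df = 1L, lower.tail = FALSE),
       expected_counts = unname(expected))
}

#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Per-marker population-genetic summary
#'
#' One row per marker: allele frequencies, genotype counts and frequencies,
#' Hardy-Weinberg chi-square test, and the diversity indices of
#' [diversity_indices()].
#'
#' The chi-square test always uses exact count-derived allele frequencies.
#' For the diversity indices, `freq_digits` controls the precision of the
#' frequencies they are computed from: the default (`2`) evaluates them at
#' the two-decimal precision at which allele frequencies are conventionally
#' reported, so the printed indices are exactly reproducible from the printed
#' frequencies; `freq_digits = NULL` uses the exact frequencies instead.
#'
#' @param genotypes Data frame with columns `animal_id`, `marker`,
#'   `genotype`, or a list of `genotype_counts` objects.
#' @param alleles Optional named list mapping marker name to its allele pair;
#'   if omitted, alleles are inferred from the observed calls (sorted).
#' @param freq_digits Integer or `NULL`, see Details.
#' @return Data frame with one row per marker and columns `marker`,
#'   `allele_first`, `allele_second`, `p_first`, `p_second`, `n`,
#'   `n_hom_first`, `n_het`, `n_hom_second`, `chi2`, `df`, `p_hwe`, `stars`,
#'   `Ho`, `He`, `Ne`, `PIC`, `MAF`.
#' @export
popgen_summary <- function(genotypes, alleles = NULL, freq_digits = 2) {
  counts_list <- if (is.data.frame(genotypes)) {
    stopifnot(all(c("marker", "genotype") %in% names(genotypes)))
    lapply(split(genotypes, genotypes$marker), function(d) {
      m <- as.character(d$marker[1])
      al <- if (!is.null(alleles)) alleles[[m]] else
        sort(unique(unlist(strsplit(as.character(d$genotype), ""))))
      if (length(al) == 1L) al <- c(al, al) # degenerate, caught in hwe_test
      count_genotypes(as.character(d$genotype), al, marker = m)
    })
  } else {
    stopifnot(all(vapply(genotypes, inherits, TRUE, "genotype_counts")))
    stats::setNames(genotypes, vapply(genotypes, `[[`, "", "marker"))
  }
  rows <- lapply(counts_list, function(ct) {
    p <- allele_frequencies(ct)
    hwe <- hwe_test(ct)
    pr <- if (is.null(freq_digits)) p else {
      r <- round(p[1], freq_digits)
      stats::setNames(c(r, 1 - r), names(p))
    }
    di <- diversity_indices(pr)
    data.frame(
      marker = ct$marker,
      allele_first = ct$alleles[1], allele_second = ct$alleles[2],
      p_first = unname(p[1]), p_second = unname(p[2]), n = ct$n,
      n_hom_first = ct$counts[["hom_first"]], n_het = ct$counts[["het"]],
      n_hom_second = ct$counts[["hom_second"]],
      chi2 = hwe$chi2, df = hwe$df, p_hwe = hwe$p_value,
      stars = significance_stars(hwe$p_value),
      Ho = di$Ho, He = di$He, Ne = di$Ne, PIC = di$PIC, MAF = di$MAF,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
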