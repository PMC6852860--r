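#' Single-locus additive effect
#'
#' Half the difference between the two homozygote means, in the trait's
#' units, under the convention
#' `a = (mean_hom_second - mean_hom_first) / 2` with genotypes ordered by
#' lexically sorted alleles (so for a C/T marker, `a = (TT - CC) / 2`).
#'
#' @param mean_hom_first,mean_hom_second Means (typically least-square
#'   means) of the first- and second-allele homozygotes.
#' @return Additive effect `a`.
#' @examples
#' additive_effect(231.47, 214.13) # -8.67
#' @export
additive_effect <- function(mean_hom_first, mean_hom_second) {
  if (is.na(mean_hom_first) || is.na(mean_hom_second)) {
    stop(not_estimable("additive effect needs both homozygote means"))
  }
  (mean_hom_second - mean_hom_first) / 2
}

#' Single-locus dominance deviation
#'
#' Deviation of the heterozygote mean from the midpoint of the two
#' homozygote means: `d = mean_het - (mean_hom_first + mean_hom_second) / 2`.
#'
#' @param mean_het Heterozygote mean.
#' @inheritParams additive_effect
#' @return Dominance deviation `d`.
#' @examples
#' dominance_effect(428.14, 474.54, 447.82) # -33.04
#' @export
dominance_effect <- function(mean_het, mean_hom_first, mean_hom_second) {
  if (is.na(mean_het) || is.na(mean_hom_first) || is.na(mean_hom_second)) {
    stop(not_estimable("dominance deviation needs all three genotype means"))
  }
  mean_het - (mean_hom_first + mean_hom_second) / 2
}

not_estimable <- function(msg) {
  structure(class = c("fattenassoc_not_estimable", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Degree of dominance
#'
#' The ratio `d / a`, flagged undefined (returned as `NA`, no division
#' attempted) when `|a|` does not exceed `tolerance`. `|d/a| < 1` indicates
#' partial dominance, `~1` complete dominance, `> 1` overdominance.
#'
#' @param a Additive effect.
#' @param d Dominance deviation.
#' @param tolerance Magnitude below which `a` counts as zero (choose about
#'   1e-9 of the trait's scale).
#' @return `d / a`, or `NA` when undefined.
#' @export
degree_of_dominance <- function(a, d, tolerance = 1e-9) {
  if (is.na(a) || abs(a) <= tolerance) return(NA_real_)
  d / a
}

#' Additive/dominance decomposition of a genotype-means table
#'
#' For each marker x trait cell of a long least-square-means table, computes
#' the additive effect, dominance deviation and degree of dominance from the
#' three genotype means, carrying the genotype-term p-value where supplied.
#' Markers missing a genotype class (e.g. a homozygote class absent from the
#' cohort) are flagged `not_estimable` rather than dropped.
#'
#' The homozygote order follows the marker's allele pair when `alleles` is
#' given, otherwise the lexical order of the genotype strings.
#'
#' @param lsm Long data frame with columns `marker`, `genotype`, `trait`,
#'   `lsm` (e.g. from [marker_lsm_table()] or [holstein_trait_lsm()]).
#' @param pvalues Optional data frame `marker`, `trait`, `p` with the
#'   genotype-term p-values to carry into the output.
#' @param alleles Optional named list mapping marker to its ordered allele
#'   pair.
#' @param tolerance Passed to [degree_of_dominance()].
#' @return Data frame `trait`, `marker`, `additive`, `dominance`, `degree`,
#'   `overall_p`, `stars`, `estimable`.
#' @export
gene_action_table <- function(lsm, pvalues = NULL, alleles = NULL,
                              tolerance = 1e-9) {
  stopifnot(all(c("marker", "genotype", "trait", "lsm") %in% names(lsm)))
  lsm$genotype <- normalize_genotype(as.character(lsm$genotype))
  cells <- unique(lsm[, c("marker", "trait")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    m <- cells$marker[i]; tr <- cells$trait[i]
    d <- lsm[lsm$marker == m & lsm$trait == tr, ]
    al <- if (!is.null(alleles) && !is.null(alleles[[m]])) alleles[[m]] else
      sort(unique(unlist(strsplit(d$genotype, ""))))
    g1 <- paste0(al[1], al[1])
    g2 <- paste0(al[2], al[2])
    ghet <- normalize_genotype(paste0(al[1], al[2]))
    pick <- function(g) {
      v <- d$lsm[d$genotype == g]
      if (length(v) == 1) v else NA_real_
    }
    a <- tryCatch(additive_effect(pick(g1), pick(g2)),
                  fattenassoc_not_estimable = function(e) NA_real_)
    dd <- tryCatch(dominance_effect(pick(ghet), pick(g1), pick(g2)),
                   fattenassoc_not_estimable = function(e) NA_real_)
    p <- NA_real_
    if (!is.null(pvalues)) {
      hit <- pvalues$marker == m & pvalues$trait == tr
      if (any(hit)) p <- pvalues$p[hit][1]
    } else if ("p_genotype" %in% names(d)) {
      p <- d$p_genotype[1]
    }
    data.frame(trait = tr, marker = m, additive = a, dominance = dd,
               degree = degree_of_dominance(a, dd, tolerance),
               overall_p = p,
               stars = if (is.na(p)) "" else significance_stars(p),
               estimable = !is.na(a) && !is.na(dd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
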