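#' Packaged reference tables
#'
#' `holstein_genotype_counts()` returns the per-marker genotype counts of a
#' genotyped cohort of 296 Holstein-Friesian fattening bulls (15 biallelic
#' SNP markers; the OLR1 marker has no second-allele homozygote in this
#' cohort). `holstein_trait_lsm()` returns the corresponding published
#' genotype least-square means (with standard errors) for 30 fattening
#' performance traits. Both ship with the package so the population-genetic
#' and gene-action stages can be exercised on real summary data without any
#' raw-record download.
#'
#' @return A data frame (`marker`, `allele_first`, `allele_second`,
#'   `hom_first`, `het`, `hom_second` for the counts; `marker`, `genotype`,
#'   `trait`, `lsm`, `se` for the means).
#' @export
holstein_genotype_counts <- function() {
  utils::read.csv(system.file("extdata", "holstein_genotype_counts.csv",
                              package = "fattenassoc"),
                  stringsAsFactors = FALSE)
}

#' @rdname holstein_genotype_counts
#' @export
holstein_trait_lsm <- function() {
  utils::read.csv(system.file("extdata", "holstein_trait_lsm.csv",
                              package = "fattenassoc"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' Population-genetic summary from a published counts table
#'
#' Fixture-mode entry point: runs [popgen_summary()] on a counts table in
#' the [holstein_genotype_counts()] layout, yielding the diversity /
#' Hardy-Weinberg table for a cohort whose raw calls are not available.
#'
#' @param counts_df Data frame with columns `marker`, `allele_first`,
#'   `allele_second`, `hom_first`, `het`, `hom_second`.
#' @inheritParams popgen_summary
#' @return See [popgen_summary()].
#' @export
popgen_summary_from_counts <- function(counts_df, freq_digits = 2) {
  cl <- lapply(seq_len(nrow(counts_df)), function(i) {
    r <- counts_df[i, ]
    genotype_counts(r$hom_first, r$het, r$hom_second,
                    c(r$allele_first, r$allele_second), marker = r$marker)
  })
  popgen_summary(cl, freq_digits = freq_digits)
}

log_stage <- function(verbose, ...) {
  if (verbose) message("[fattenassoc] ", ...)
}

#' Run the full pipeline
#'
#' Orchestrates simulate -> write -> derive traits -> population genetics ->
#' association scan -> per-marker LSM tables -> gene action, writing each
#' stage's CSV into `out_dir` and logging row counts, exclusions
#' (animals that never reached a target, interaction combinations below
#' `min_count`) and the seed. Re-running with the same config reproduces
#' every output byte for byte.
#'
#' @param config Either a list or a path to a YAML file with (all optional)
#'   fields `seed`, `n_animals`, `herd_dir`, `out_dir`, `targets`, `alpha`,
#'   `min_count`, `interactions` (list of marker-name vectors), `markers`
#'   (restrict the scan), `verbose`. When `herd_dir` holds an existing herd
#'   and `simulate` is `FALSE`, that herd is analysed instead of a fresh
#'   simulation.
#' @param simulate Generate a synthetic herd (default `TRUE`) or read one
#'   from `config$herd_dir`.
#' @return Invisibly, a list with the herd, the traits table, the popgen
#'   summary, the association scan, the LSM tables, the gene-action table
#'   and the exclusion log.
#' @export
run_pipeline <- function(config = list(), simulate = TRUE) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% tempfile("fattenassoc_run_")
  targets <- config$targets %||% c(100, 200, 300, 400, 450)
  alpha <- config$alpha %||% 0.05
  min_count <- config$min_count %||% 3
  verbose <- config$verbose %||% TRUE
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (simulate) {
    cfg <- herd_config(n_animals = config$n_animals %||% 296,
                       target_weights = targets, seed = seed)
    log_stage(verbose, "simulate: n=", cfg$n_animals, " seed=", seed)
    herd <- simulate_herd(cfg)
    herd_dir <- config$herd_dir %||% file.path(out_dir, "herd")
    write_herd(herd, herd_dir)
    log_stage(verbose, "simulate: wrote ", herd_dir)
  } else {
    herd_dir <- config$herd_dir %||% stop("herd_dir required when not",
                                          " simulating")
    herd <- read_herd(herd_dir)
    log_stage(verbose, "read herd from ", herd_dir, ": ",
              nrow(herd$animals), " animals")
  }

  traits <- derive_traits(herd, targets = targets)
  excl <- attr(traits, "exclusions")
  log_stage(verbose, "traits: ", nrow(traits), " animals, ",
            nrow(excl), " exclusion records")
  if (nrow(excl) > 0 && verbose) {
    for (i in seq_len(nrow(excl))) {
      log_stage(verbose, "exclude animal=", excl$animal_id[i],
                " target=", excl$target[i], " reason=", excl$reason[i])
    }
  }
  utils::write.csv(traits, file.path(out_dir, "traits.csv"),
                   row.names = FALSE)

  pg <- popgen_summary(herd$genotypes)
  utils::write.csv(pg, file.path(out_dir, "popgen_summary.csv"),
                   row.names = FALSE)
  log_stage(verbose, "popgen: ", nrow(pg), " markers")

  markers <- config$markers %||% unique(herd$genotypes$marker)
  scan <- assoc_scan(traits, herd$genotypes, markers = markers,
                     alpha = alpha)
  utils::write.csv(scan, file.path(out_dir, "assoc_pvalues.csv"),
                   row.names = FALSE)
  log_stage(verbose, "assoc: ", length(markers), " markers x ",
            length(unique(scan$trait)), " traits")

  lsm_all <- list()
  for (m in markers) {
    lt <- marker_lsm_table(traits, herd$genotypes, m, alpha = alpha)
    if (is.null(lt)) next
    lsm_all[[m]] <- lt
    safe <- gsub("[^A-Za-z0-9_.-]", "_", m)
    utils::write.csv(lt, file.path(out_dir, paste0("lsm_", safe, ".csv")),
                     row.names = FALSE)
  }
  lsm_long <- do.call(rbind, lsm_all)
  rownames(lsm_long) <- NULL

  interactions <- config$interactions %||% list()
  inter_rows <- list()
  for (pair in interactions) {
    for (tr in unique(scan$trait)) {
      res <- tryCatch({
        fit <- fit_interaction(traits, herd$genotypes, pair, tr,
                               min_count = min_count, alpha = alpha)
        if (nrow(fit$excluded_combinations) > 0 && verbose) {
          log_stage(verbose, "interaction ", paste(pair, collapse = "x"),
                    " trait=", tr, ": excluded low-count combinations ",
                    paste(fit$excluded_combinations$combination,
                          collapse = ", "))
        }
        lsm <- least_square_means(fit)
        p <- fit$f_tests$p[fit$f_tests$term == "genotype"]
        data.frame(interaction = paste(pair, collapse = "x"), trait = tr,
                   combination = lsm$level, lsm = lsm$lsm, se = lsm$se,
                   p_genotype = p, n = fit$n_used,
                   stringsAsFactors = FALSE)
      }, error = function(e) NULL)
      if (!is.null(res)) inter_rows[[length(inter_rows) + 1L]] <- res
    }
  }
  inter <- if (length(inter_rows)) do.call(rbind, inter_rows) else NULL
  if (!is.null(inter)) {
    utils::write.csv(inter, file.path(out_dir, "interactions.csv"),
                     row.names = FALSE)
  }

  ga <- if (!is.null(lsm_long)) gene_action_table(lsm_long) else NULL
  if (!is.null(ga)) {
    utils::write.csv(ga, file.path(out_dir, "gene_action.csv"),
                     row.names = FALSE)
    log_stage(verbose, "gene action: ", nrow(ga), " marker x trait cells")
  }

  invisible(list(herd = herd, traits = traits, popgen = pg, scan = scan,
                 lsm = lsm_long, interactions = inter, gene_action = ga,
                 exclusions = excl, out_dir = out_dir, seed = seed))
}
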