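#' Pipeline configuration
#'
#' Bundles a simulation config with downstream stage parameters for
#' [run_pipeline()].
#'
#' @param sim A [sim_config()].
#' @param budget,min_loci Parentage exclusion parameters.
#' @param h1_reps,h2_reps Replicates for the hypothesis harnesses (0
#'   disables one).
#' @param fg_method,fg_reps Expected-false-Gtrio method and Monte-Carlo
#'   replicates.
#' @param crr Optional tibble (`cohort`, `base_crr`, `n_females`) enabling
#'   CRR updates in the life-history stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim, budget = 1, min_loci = 9, h1_reps = 20,
                       h2_reps = 20, fg_method = "analytic", fg_reps = 200,
                       crr = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  structure(list(sim = sim, budget = budget, min_loci = min_loci,
                 h1_reps = h1_reps, h2_reps = h2_reps,
                 fg_method = fg_method, fg_reps = fg_reps, crr = crr),
            class = "run_config")
}

config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %%
            .Machine$integer.max)
}

write_stage_file <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seed: ", seed, " config: ", hash), con)
  df <- as.data.frame(df)
  for (j in seq_along(df)) if (is.list(df[[j]])) {
    df[[j]] <- vapply(df[[j]], paste, character(1), collapse = ",")
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_stage_file <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      comment.char = "#",
                                      stringsAsFactors = FALSE))
}

stage_path <- function(out_dir, name) file.path(out_dir, paste0(name, ".tsv"))

require_artifact <- function(out_dir, name, stage) {
  p <- stage_path(out_dir, name)
  if (!file.exists(p)) {
    stop("stage '", stage, "' requires missing upstream artifact '",
         basename(p), "' — run the producing stage first")
  }
  p
}

#' Run the end-to-end analysis pipeline
#'
#' Executes simulate -> parentage -> hypotheses -> gtrio -> lifehistory in
#' order, skipping unselected stages; every stage reads its inputs from and
#' writes plain delimited artifacts to `out_dir`, so any stage can be
#' re-run from persisted intermediates. Output files carry the seed and a
#' config hash in a comment line. Funnel counts (candidate >= confirmed >=
#' retained) are asserted and logged.
#'
#' @param config A [run_config()].
#' @param stages Subset of
#'   `c("simulate", "parentage", "hypotheses", "gtrio", "lifehistory")`.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "parentage", "hypotheses",
                                    "gtrio", "lifehistory"),
                         out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seed <- config$sim$seed
  say <- function(...) if (!quiet) message(...)
  paths <- list()
  put <- function(df, name) {
    p <- write_stage_file(df, stage_path(out_dir, name), seed, hash)
    paths[[name]] <<- p
    p
  }
  roles <- NULL

  if ("simulate" %in% stages) {
    say("simulate: ", length(config$sim$years), " cohort year(s)")
    sim <- simulate_population(config$sim)
    write_panel(sim$adults, stage_path(out_dir, "adults"))
    write_panel(sim$offspring, stage_path(out_dir, "offspring"))
    paths$adults <- stage_path(out_dir, "adults")
    paths$offspring <- stage_path(out_dir, "offspring")
    put(sim$adults$loci, "loci")
    put(sim$truth$parents, "truth_parents")
    if (nrow(sim$truth$roster)) put(sim$truth$roster, "truth_roster")
  }

  load_panels <- function(stage) {
    lp <- read_stage_file(require_artifact(out_dir, "loci", stage))
    roles <<- stats::setNames(lp$role, lp$locus)
    list(adults = load_panel(require_artifact(out_dir, "adults", stage),
                             roles = roles),
         offspring = load_panel(require_artifact(out_dir, "offspring", stage),
                                roles = roles))
  }

  if ("parentage" %in% stages) {
    pan <- load_panels("parentage")
    say("parentage: ", n_ind(pan$offspring), " offspring vs ",
        n_ind(pan$adults), " adults")
    asn <- assign_parents(pan$adults, pan$offspring, budget = config$budget,
                          min_loci = config$min_loci)
    put(asn, "assignments")
    put(categorize(asn), "category_summary")
    put(extract_mate_pairs(asn), "mate_pairs")
    sx <- strict_sex_search(asn, pan$adults, pan$offspring)
    put(sx$tally, "sex_search_tally")
    if (nrow(sx$flips)) put(sx$flips, "sex_flips")
  }

  if ("hypotheses" %in% stages) {
    pan <- load_panels("hypotheses")
    freqs <- allele_frequencies(pan$adults, "primary")
    n_f <- sum(pan$adults$ind$sex == "female")
    n_m <- sum(pan$adults$ind$sex == "male")
    res <- list()
    if (config$h1_reps > 0) {
      say("hypotheses: H1, ", config$h1_reps, " replicate(s)")
      res[[length(res) + 1L]] <-
        simulate_h1(freqs, n_f, n_m, n_ind(pan$offspring),
                    config$sim$error_rate, reps = config$h1_reps,
                    seed = seed + 1L, budget = config$budget,
                    min_loci = config$min_loci)
    }
    if (config$h2_reps > 0) {
      say("hypotheses: H2, ", config$h2_reps, " replicate(s)")
      res[[length(res) + 1L]] <-
        simulate_h2(freqs, n_f, n_m, n_ind(pan$offspring),
                    config$sim$remove_females, config$sim$remove_males,
                    reps = config$h2_reps, seed = seed + 2L,
                    budget = config$budget, min_loci = config$min_loci)
    }
    if (length(res)) put(dplyr::bind_rows(res), "hypotheses")
  }

  if ("gtrio" %in% stages) {
    pan <- load_panels("gtrio")
    asn <- read_stage_file(require_artifact(out_dir, "assignments", "gtrio"))
    pairs <- read_stage_file(require_artifact(out_dir, "mate_pairs", "gtrio"))
    cand <- find_gtrios(pairs, asn, pan$adults, pan$offspring)
    conf <- confirm_gtrios(cand, pan$adults, pan$offspring)
    res <- resolve_ambiguities(conf)
    say("gtrio funnel: ", nrow(cand), " candidate / ",
        sum(conf$status == "confirmed"), " confirmed / ",
        nrow(res$retained), " retained")
    stopifnot(nrow(cand) >= sum(conf$status == "confirmed"),
              sum(conf$status == "confirmed") >= nrow(res$retained))
    put(conf, "gtrios")
    put(res$retained, "gtrios_retained")
    freqs <- allele_frequencies(pan$adults, "primary")
    fg <- expected_false_gtrios(pairs, asn, pan$adults, pan$offspring, freqs,
                                method = config$fg_method,
                                reps = config$fg_reps, seed = seed + 3L)
    put(tibble::tibble(expectation = fg$expectation, se = fg$se,
                       n_pairs = fg$n_pairs, n_offspring = fg$n_offspring,
                       method = fg$method), "gtrio_expectation")
  }

  if ("lifehistory" %in% stages) {
    ret <- read_stage_file(require_artifact(out_dir, "gtrios_retained",
                                            "lifehistory"))
    adults <- infer_unsampled_adults(ret)
    put(adults, "unsampled_adults")
    sm <- summarize_adults(adults)
    put(sm$table, "unsampled_summary")
    say("lifehistory: ", sm$totals$total, " unsampled adult(s) (",
        sm$totals$precocial, " precocial, ", sm$totals$adfluvial,
        " adfluvial)")
    if (length(unique(adults$sex)) == 2) {
      ac <- compare_ages(adults)
      put(tibble::tibble(male_median = ac$male_median,
                         female_median = ac$female_median,
                         statistic = ac$statistic, p_value = ac$p_value),
          "age_comparison")
    }
    if (!is.null(config$crr)) {
      crr <- lapply(seq_len(nrow(config$crr)), function(i) {
        row <- config$crr[i, ]
        n_adf <- sum(adults$sex == "female" & adults$tactic == "adfluvial" &
                     adults$cohort == row$cohort)
        cbind(cohort = row$cohort,
              update_crr(row$base_crr, row$n_females, n_adf))
      })
      put(dplyr::bind_rows(crr), "crr")
    }
  }
  invisible(paths)
}
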