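PIPELINE_STAGES <- c("simulate", "phenotypes", "associations", "milestones",
                     "dnm", "enrichment", "scores")

#' Synthetic per-gene mutation-rate table
#'
#' Generates a scaled-down exome: per-gene synonymous rates drawn from a
#' gamma distribution around `mean_syn_rate`, missense and
#' protein-truncating rates in fixed proportions (2.2x and 0.35x the
#' synonymous rate, mirroring the relative target sizes of the classes),
#' and the first 20% of genes tagged as DD-associated (DDG2P).
#'
#' @param n_genes Number of genes.
#' @param mean_syn_rate Mean per-gene synonymous rate (expected synonymous
#'   DNMs per proband).
#' @param seed Integer seed.
#' @return Gene rate table (`gene`, `class`, `mu`, `ddg2p`).
#' @export
synthetic_gene_rates <- function(n_genes = 100, mean_syn_rate = 0.0025,
                                 seed = 1) {
  with_substream(seed, "rates", {
    genes <- sprintf("G%04d", seq_len(n_genes))
    syn <- stats::rgamma(n_genes, shape = 2, rate = 2 / mean_syn_rate)
    ddg2p <- seq_len(n_genes) <= ceiling(0.2 * n_genes)
    rates <- rbind(
      data.frame(gene = genes, class = "synonymous", mu = syn, ddg2p = ddg2p),
      data.frame(gene = genes, class = "missense", mu = 2.2 * syn, ddg2p = ddg2p),
      data.frame(gene = genes, class = "ptv", mu = 0.35 * syn, ddg2p = ddg2p))
    rownames(rates) <- NULL
    validate_gene_rates(rates)
  })
}

#' Validate a pipeline configuration
#'
#' Schema-checks a YAML configuration (or an equivalent list): stage
#' toggles, a non-negative integer seed, an output directory, and — for each
#' enabled stage — the presence of the input files it depends on. All
#' problems are reported at once.
#'
#' @param config Path to a YAML file, or a list.
#' @return A validated `run_config` list (errors otherwise).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_config("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  errs <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)

  known <- c("seed", "outdir", "n_probands", "stages", "inputs",
             "dnm_excess", "milestone_params", "trio_params")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    errs <- c(errs, paste0("unknown config keys: ",
                           paste(unknown, collapse = ", ")))
  seed <- config$seed
  need(is.numeric(seed) && length(seed) == 1 && seed >= 0 &&
         seed == floor(seed), "seed: must be a non-negative integer")
  need(is.character(config$outdir) && length(config$outdir) == 1,
       "outdir: must be a single path")
  stages <- config$stages %||% list()
  bad_stage <- setdiff(names(stages), PIPELINE_STAGES)
  if (length(bad_stage))
    errs <- c(errs, paste0("unknown stages: ",
                           paste(bad_stage, collapse = ", ")))
  on <- function(s) isTRUE(stages[[s]])
  inputs <- config$inputs %||% list()
  need_input <- function(stage, key) {
    if (!on(stage)) return(invisible())
    path <- inputs[[key]]
    if (is.null(path))
      errs <<- c(errs, paste0(stage, " stage enabled but inputs$", key,
                              " is missing"))
    else if (!file.exists(path))
      errs <<- c(errs, paste0("inputs$", key, ": file not found: ", path))
  }
  if (!on("simulate")) {
    for (s in c("phenotypes", "associations", "milestones", "dnm",
                "enrichment", "scores"))
      need_input(s, "cohort")
  } else {
    need(is.numeric(config$n_probands) && config$n_probands >= 0,
         "n_probands: required (>= 0) when simulate stage is enabled")
  }
  need_input("phenotypes", "ontology")
  if (on("phenotypes") && is.null(config$inputs$system_roots))
    errs <- c(errs, "phenotypes stage enabled but inputs$system_roots is missing")
  if (on("enrichment")) need_input("enrichment", "gene_sets")
  if (length(errs))
    stop_config("invalid configuration:\n  - ",
                paste(errs, collapse = "\n  - "))
  config$stages <- stages
  class(config) <- "run_config"
  config
}

stage_on <- function(config, s) isTRUE(config$stages[[s]])

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order — cohort simulation or
#' loading, ontology-based phenotype derivation, the phenotype regression
#' battery, the milestone survival battery, de novo burden, diagnostic
#' enrichment, and the genetic-score analyses — writing one TSV per result
#' table plus a JSON run manifest (inputs hashed, seed, stage toggles, and
#' every multiplicity ledger).
#'
#' @param config A `run_config` (see [validate_config]) or a path to one.
#' @return Invisibly, the manifest list; side effect: files under
#'   `config$outdir`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  manifest <- list(seed = seed, stages = config$stages,
                   inputs = list(), outputs = character(0), ledgers = list())
  for (key in names(config$inputs %||% list())) {
    p <- config$inputs[[key]]
    if (is.character(p) && length(p) == 1 && file.exists(p))
      manifest$inputs[[key]] <- list(path = p, md5 = unname(tools::md5sum(p)))
  }
  emit <- function(tab, name) {
    path <- file.path(outdir, paste0(name, ".tsv"))
    write_tsv(tab, path)
    manifest$outputs <<- c(manifest$outputs, basename(path))
  }

  sc <- sim_config(n_probands = config$n_probands %||% 1000,
                   dnm_excess = unlist(config$dnm_excess %||% list()),
                   gene_sets = list(), seed = seed)

  # --- cohort -------------------------------------------------------------
  cohort <- if (stage_on(config, "simulate")) {
    ch <- simulate_cohort(sc)
    emit(ch, "cohort")
    ch
  } else {
    ch <- read_tsv(config$inputs$cohort)
    ch$prematurity_category <- factor(ch$prematurity_category,
                                      levels = PREMATURITY_LEVELS)
    ch
  }

  # --- ontology phenotypes ------------------------------------------------
  if (stage_on(config, "phenotypes")) {
    graph <- read_obo(config$inputs$ontology)
    roots <- unlist(config$inputs$system_roots)
    osmap <- assign_organ_systems(graph, roots)
    term_list <- strsplit(cohort$hpo_terms %||% "", ";", fixed = TRUE)
    cohort$n_affected_systems <- vapply(term_list, function(tt)
      count_affected_systems(tt[nzchar(tt)], osmap), integer(1))
    emit(data.frame(proband_id = cohort$proband_id,
                    n_affected_systems = cohort$n_affected_systems),
         "organ_system_counts")
  }

  # --- phenotype association battery -------------------------------------
  if (stage_on(config, "associations")) {
    cohort$low_birthweight <- as.integer(cohort$birthweight_g < 2500)
    specs <- list(
      model_spec("low_birthweight", "binary", covariates = "postnatal"),
      model_spec("birthweight_g", "continuous", covariates = "postnatal"))
    fits <- lapply(specs, function(sp) {
      base <- fit_phenotype_model(cohort, sp)
      inter <- fit_interaction_model(cohort, sp)
      base$model <- paste0(sp$outcome, ":base")
      inter$model <- paste0(sp$outcome, ":interaction")
      rbind(base, inter)
    })
    assoc <- do.call(rbind, fits)
    emit(assoc, "associations")
    n_tests <- sum(grepl("prematurity", assoc$term))
    manifest$ledgers$associations <- list(
      n_tests = n_tests, threshold = bonferroni_threshold(max(n_tests, 1)))
  }

  # --- milestones ---------------------------------------------------------
  if (stage_on(config, "milestones")) {
    mp <- config$milestone_params
    if (!is.null(mp)) {
      sc$milestone_params <- utils::modifyList(sc$milestone_params, mp)
      if (!is.null(mp$baseline_median_months))
        sc$milestone_params$baseline_median_months <-
          unlist(mp$baseline_median_months)
      if (!is.null(mp$log_hr_by_category))
        sc$milestone_params$log_hr_by_category <-
          unlist(mp$log_hr_by_category)
    }
    cohort_ms <- simulate_milestones(cohort, sc)
    mb <- milestone_battery(cohort_ms)
    km_tab <- do.call(rbind, lapply(names(mb$milestones), function(m)
      data.frame(milestone = m, chisq = mb$milestones[[m]]$km$chisq,
                 df = mb$milestones[[m]]$km$df, p = mb$milestones[[m]]$km$p)))
    cox_tab <- do.call(rbind, lapply(names(mb$milestones), function(m)
      cbind(milestone = m, mb$milestones[[m]]$cox)))
    emit(km_tab, "milestones_logrank")
    emit(cox_tab, "milestones_cox")
    manifest$ledgers$milestones <- mb$ledgers
  }

  # --- de novo burden -----------------------------------------------------
  if (stage_on(config, "dnm")) {
    rates <- if (!is.null(config$inputs$rates))
      read_gene_rates(config$inputs$rates)
    else synthetic_gene_rates(seed = seed)
    excess <- unlist(config$dnm_excess %||% list())
    sc_dnm <- sc
    if (length(excess)) {
      ddg2p <- unique(rates$gene[rates$ddg2p])
      sc_dnm$gene_sets <- list(ddg2p = ddg2p)
      sc_dnm$dnm_excess <- excess[intersect(names(excess), "ddg2p")]
    }
    dnms <- simulate_dnms(cohort, rates, sc_dnm)
    emit(dnms, "dnms")
    burden <- run_dnm_analysis(cohort, dnms, rates)
    emit(burden$strata, "dnm_burden")
    emit(burden$comparisons, "dnm_af_comparisons")
    manifest$ledgers$dnm <- burden$ledgers
  }

  # --- diagnostic enrichment ----------------------------------------------
  if (stage_on(config, "enrichment")) {
    gene_sets <- read_gmt(config$inputs$gene_sets)
    rates <- if (!is.null(config$inputs$rates))
      read_gene_rates(config$inputs$rates)
    else synthetic_gene_rates(seed = seed)
    diag_tab <- with_substream(seed, "diaggenes", {
      d <- cohort[cohort$diagnosed == 1,
                  c("proband_id", "prematurity_category", "cohort_label")]
      d$gene <- sample(unique(rates$gene), nrow(d), replace = TRUE)
      d$preterm <- as.integer(d$prematurity_category != "term")
      d$tier <- sample(c("confirmed", "broader"), nrow(d), replace = TRUE,
                       prob = c(0.8, 0.2))
      d
    })
    genes <- select_testable_genes(diag_tab)
    per_gene <- do.call(rbind, lapply(genes, function(g)
      per_gene_prematurity_association(diag_tab, g)))
    if (!is.null(per_gene)) emit(per_gene, "per_gene_enrichment")
    gsf <- gene_set_fisher(diag_tab, gene_sets)
    emit(gsf$overall, "gene_set_overall")
    emit(gsf$pairwise, "gene_set_pairwise")
    manifest$ledgers$enrichment <- list(
      per_gene = list(n_tests = length(genes),
                      threshold = bonferroni_threshold(max(length(genes), 1))),
      gene_set = gsf$ledger)
  }

  # --- genetic scores -----------------------------------------------------
  if (stage_on(config, "scores")) {
    if (!is.null(config$trio_params))
      sc$trio_params <- utils::modifyList(sc$trio_params, config$trio_params)
    trio <- simulate_trios(cohort, sc)
    td <- trio_decomposition(trio$scores$child, trio$scores$mother,
                             trio$scores$father, trio$phenotype)
    emit(td, "trio_decomposition")
  }

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
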