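#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end survey in one place.
#' Thresholds default to the survey's canonical values: best-hit identity
#' 0.65 with both-sided coverage 0.8, a +/- 5 gene neighborhood window,
#' adjusted-p significance 0.05, high-quality completeness cut 0.90, minimum
#' 10 genomes per phylum, top-20 core defensome, and a 3% prevalence floor
#' for per-system models.
#'
#' @param output_dir Directory the pipeline writes to.
#' @param seed Master seed; every stage's randomness derives from it.
#' @param n_genomes Genomes in the simulated RM cohort.
#' @param n_refs_per_role Reference catalogue entries per (type, role).
#' @param identity Planted RM component identity.
#' @param completeness Gene retention probability for the RM cohort.
#' @param n_decoys Decoy genes per genome.
#' @param n_dms,n_vspr,tool_rm_fraction Tool-output decoy/overlap knobs
#'   (see [plan_genome()]).
#' @param min_identity,min_coverage,window RM detection thresholds.
#' @param alpha,hq_completeness,min_phylum_n,core_k,prevalence_floor
#'   Statistical thresholds.
#' @param rm_name_pattern Regular expression marking RM system names.
#' @param cohort A [cohort_config()] for the statistical cohort.
#' @return A list of class `defensome_config`.
#' @export
defensome_config <- function(output_dir = tempfile("defensome_run_"),
                             seed = 1L,
                             n_genomes = 30L,
                             n_refs_per_role = 2L,
                             identity = 0.75,
                             completeness = 1,
                             n_decoys = 12L,
                             n_dms = 1L,
                             n_vspr = 1L,
                             tool_rm_fraction = 0.5,
                             min_identity = 0.65,
                             min_coverage = 0.8,
                             window = 5L,
                             alpha = 0.05,
                             hq_completeness = 0.90,
                             min_phylum_n = 10L,
                             core_k = 20L,
                             prevalence_floor = 0.03,
                             rm_name_pattern = DEFAULT_RM_NAMES,
                             cohort = cohort_config()) {
  checks <- list(
    n_genomes = c(n_genomes, 1, Inf),
    n_refs_per_role = c(n_refs_per_role, 1, Inf),
    identity = c(identity, 1e-9, 1),
    completeness = c(completeness, 1e-9, 1),
    min_identity = c(min_identity, 0, 1),
    min_coverage = c(min_coverage, 0, 1),
    window = c(window, 1, Inf),
    alpha = c(alpha, 0, 1),
    hq_completeness = c(hq_completeness, 0, 1),
    min_phylum_n = c(min_phylum_n, 1, Inf),
    core_k = c(core_k, 1, Inf),
    prevalence_floor = c(prevalence_floor, 0, 1)
  )
  for (nm in names(checks)) {
    v <- checks[[nm]]
    if (!is.numeric(v[1]) || !is.finite(v[1]) || v[1] < v[2] || v[1] > v[3]) {
      abort(sprintf("config field `%s` is out of range.", nm),
        class = "defensome_validation_error"
      )
    }
  }
  structure(
    list(
      output_dir = output_dir, seed = as.integer(seed),
      n_genomes = as.integer(n_genomes),
      n_refs_per_role = as.integer(n_refs_per_role),
      identity = identity, completeness = completeness,
      n_decoys = as.integer(n_decoys), n_dms = as.integer(n_dms),
      n_vspr = as.integer(n_vspr), tool_rm_fraction = tool_rm_fraction,
      min_identity = min_identity, min_coverage = min_coverage,
      window = as.integer(window), alpha = alpha,
      hq_completeness = hq_completeness,
      min_phylum_n = as.integer(min_phylum_n), core_k = as.integer(core_k),
      prevalence_floor = prevalence_floor,
      rm_name_pattern = rm_name_pattern, cohort = cohort
    ),
    class = "defensome_config"
  )
}

# Stable hash of the config (output paths excluded so relocating a run does
# not change its identity).
config_hash <- function(config) {
  x <- unclass(config)
  x$output_dir <- NULL
  rlang::hash(x)
}

stage_log <- function(stage, t0) {
  message(sprintf(
    "[defensome] %s finished in %.1fs", stage,
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ))
}

# Deterministic in-memory simulation shared by run_simulate / run_detect.
simulate_inputs <- function(config) {
  refdb <- generate_reference_db(
    n_per_role = config$n_refs_per_role, seed = derive_seed(config$seed, 101)
  )
  extra <- tibble::tibble(
    system_name = c("CBASS", "viperin"), rm_type = NA_character_, n_genes = 2L
  )
  cohort <- simulate_rm_cohort(
    n_genomes = config$n_genomes, refdb = refdb,
    identity = config$identity, completeness = config$completeness,
    n_decoys = config$n_decoys, extra_systems = extra,
    n_dms = config$n_dms, n_vspr = config$n_vspr,
    tool_rm_fraction = config$tool_rm_fraction,
    seed = derive_seed(config$seed, 202)
  )
  plan_stub <- plan_genome("stub",
    n_dms = config$n_dms, n_vspr = config$n_vspr,
    tool_rm_fraction = config$tool_rm_fraction
  )
  tool_calls <- purrr::list_rbind(purrr::imap(
    cohort$genomes,
    function(g, i) emit_tool_calls(g, plan_stub, seed = derive_seed(config$seed, 300 + i))
  ))
  # genome metadata drawn from the cohort config's covariate distributions
  meta <- with_seed(derive_seed(config$seed, 404), {
    n <- length(cohort$genomes)
    dom <- rep(c("Archaea", "Bacteria"), length.out = n)
    ph <- config$cohort$phyla
    purrr::list_rbind(purrr::map(seq_len(n), function(i) {
      phd <- ph[ph$domain == dom[i], ]
      cb <- config$cohort$completeness_beta[[dom[i]]]
      sl <- config$cohort$size_lognorm[[dom[i]]]
      og <- config$cohort$ogt[[dom[i]]]
      ci <- sample.int(length(og$weights), 1, prob = og$weights)
      tibble::tibble(
        genome_id = cohort$genomes[[i]]$genes$genome_id[1],
        domain = dom[i],
        phylum = sample(phd$phylum, 1, prob = phd$weight),
        size_mb = stats::rlnorm(1, sl["meanlog"], sl["sdlog"]),
        completeness = config$completeness,
        ogt_c = max(0, rnorm(1, og$means[ci], og$sds[ci]))
      )
    }))
  })
  list(refdb = refdb, genomes = cohort$genomes, truth = cohort$truth,
    tool_calls = tool_calls, metadata = meta)
}

#' Run the simulation stage
#'
#' Writes the reference catalogue (FASTA), per-genome protein FASTA + GFF3,
#' the emulated tool call table (CSV), genome metadata (TSV), ground truth
#' (JSON), the statistical cohort (TSV + presence TSV), and a manifest JSON
#' carrying the config and its hash. Deterministic given (config, seed).
#'
#' @param config A `defensome_config`.
#' @return Invisibly, the manifest list.
#' @export
run_simulate <- function(config = defensome_config()) {
  t0 <- Sys.time()
  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  gdir <- file.path(out, "genomes")
  if (!dir.exists(gdir)) dir.create(gdir)

  sim <- simulate_inputs(config)
  write_reference_fasta(sim$refdb, file.path(out, "reference_db.faa"))
  purrr::walk(sim$genomes, write_genome, dir = gdir)
  write_call_table(sim$tool_calls, file.path(out, "tool_calls.csv"))
  readr::write_tsv(sim$metadata, file.path(out, "genome_metadata.tsv"))
  truth_flat <- sim$truth |>
    dplyr::mutate(
      gene_ids = purrr::map_chr(.data$gene_ids, paste, collapse = ";"),
      gene_indices = purrr::map_chr(.data$gene_indices, paste, collapse = ";"),
      roles = purrr::map_chr(.data$roles, paste, collapse = ";")
    )
  jsonlite::write_json(truth_flat, file.path(out, "ground_truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  stat <- generate_cohort(config$cohort, seed = derive_seed(config$seed, 505))
  readr::write_tsv(stat$cohort, file.path(out, "stat_cohort.tsv"))
  readr::write_tsv(stat$presence, file.path(out, "stat_presence.tsv"))

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    n_genomes = config$n_genomes,
    files = sort(c(
      "reference_db.faa", "tool_calls.csv", "genome_metadata.tsv",
      "ground_truth.json", "stat_cohort.tsv", "stat_presence.tsv",
      file.path("genomes", sort(list.files(gdir)))
    ))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  stage_log("simulate", t0)
  invisible(manifest)
}

#' Run the RM detection and defensome aggregation stage
#'
#' Reads the simulated inputs from `config$output_dir` (reference FASTA,
#' per-genome FASTA/GFF3, tool calls), runs homology assignment and the
#' neighborhood RM caller per genome, merges RM calls with the filtered
#' tool calls into the per-genome defensome, and writes `rm_calls.tsv`,
#' `rm_summary.tsv`, `defensome_calls.csv` and `cohort_table.tsv`. When
#' ground truth is present, type-level precision/recall are written to
#' `detection_metrics.json`.
#'
#' @param config A `defensome_config` whose simulate stage has run.
#' @return Invisibly, a list with the RM calls, merged calls, cohort table
#'   and metrics.
#' @export
run_detect <- function(config = defensome_config()) {
  t0 <- Sys.time()
  out <- config$output_dir
  refdb <- read_reference_fasta(file.path(out, "reference_db.faa"))
  gdir <- file.path(out, "genomes")
  fastas <- sort(list.files(gdir, pattern = "\\.faa$", full.names = TRUE))
  genomes <- purrr::map(fastas, function(f) {
    read_genome(f, sub("\\.faa$", ".gff3", f))
  })
  tool_calls <- read_call_table(file.path(out, "tool_calls.csv"))

  rm_calls <- detect_rm_cohort(
    genomes, refdb,
    external_calls = tool_calls,
    min_identity = config$min_identity, min_coverage = config$min_coverage,
    window = config$window
  )
  message(sprintf(
    "[defensome] detect: %d RM calls across %d genomes",
    nrow(rm_calls), length(genomes)
  ))
  write_rm_calls(rm_calls, file.path(out, "rm_calls.tsv"),
    summary_path = file.path(out, "rm_summary.tsv")
  )

  merged <- merge_defensome(
    filter_noncanonical(tool_calls), rm_calls,
    rm_name_pattern = config$rm_name_pattern
  )
  write_call_table(merged, file.path(out, "defensome_calls.csv"))

  metadata <- readr::read_tsv(file.path(out, "genome_metadata.tsv"),
    show_col_types = FALSE
  )
  cohort <- summarize_cohort(merged, metadata)
  readr::write_tsv(cohort, file.path(out, "cohort_table.tsv"))

  metrics <- NULL
  truth_path <- file.path(out, "ground_truth.json")
  if (file.exists(truth_path)) {
    truth <- tibble::as_tibble(jsonlite::fromJSON(truth_path)) |>
      dplyr::mutate(
        rm_type = ifelse(.data$rm_type %in% c("", NA), NA_character_, .data$rm_type)
      )
    metrics <- rm_precision_recall(rm_calls, truth)
    jsonlite::write_json(as.list(metrics), file.path(out, "detection_metrics.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  stage_log("detect", t0)
  invisible(list(
    rm_calls = rm_calls, merged = merged, cohort = cohort, metrics = metrics
  ))
}

#' Run the statistical stage
#'
#' Consumes the statistical cohort written by [run_simulate()] and produces
#' the survey's report files under `config$output_dir/stats`: full-cohort
#' and high-quality-subset prevalence tables with Wilson intervals, the
#' core defensome, defenseless fractions, per-system phylum contrasts
#' (Archaea; systems above the prevalence floor), completeness-adjusted
#' prevalence extrapolations, count-model summaries (NB-GLM on OGT with
#' percent change per 10 degC, hurdle NB, per-predictor pseudo R-squared),
#' genome-size regression with residual domain test, variance partitioning,
#' and the OGT-bin Kruskal-Wallis/Dunn analysis. Models with insufficient
#' data are skipped with a warning; the run continues.
#'
#' @param config A `defensome_config` whose simulate stage has run.
#' @return Invisibly, a list of the computed tables.
#' @export
run_stats <- function(config = defensome_config()) {
  t0 <- Sys.time()
  out <- config$output_dir
  sdir <- file.path(out, "stats")
  if (!dir.exists(sdir)) dir.create(sdir, recursive = TRUE)
  cohort <- readr::read_tsv(file.path(out, "stat_cohort.tsv"), show_col_types = FALSE)
  presence <- readr::read_tsv(file.path(out, "stat_presence.tsv"), show_col_types = FALSE)
  dat <- dplyr::left_join(presence, cohort, by = "genome_id")

  prevalence_table <- function(d) {
    d |>
      dplyr::group_by(.data$domain, .data$system_name) |>
      dplyr::summarise(
        n = dplyr::n(), n_present = sum(.data$present),
        prevalence = mean(.data$present), .groups = "drop"
      ) |>
      dplyr::rowwise() |>
      dplyr::mutate(
        ci_low = wilson_ci(.data$n_present, .data$n)[["low"]],
        ci_high = wilson_ci(.data$n_present, .data$n)[["high"]]
      ) |>
      dplyr::ungroup()
  }
  prev_full <- prevalence_table(dat)
  prev_hq <- prevalence_table(dat[dat$completeness >= config$hq_completeness, ])
  readr::write_tsv(prev_full, file.path(sdir, "prevalence_full.tsv"))
  readr::write_tsv(prev_hq, file.path(sdir, "prevalence_hq.tsv"))

  # per-system phylum contrasts within Archaea, above the prevalence floor
  arch <- dat[dat$domain == "Archaea", ]
  eligible <- prev_full |>
    dplyr::filter(.data$domain == "Archaea", .data$prevalence >= config$prevalence_floor)
  contrasts <- purrr::list_rbind(purrr::map(eligible$system_name, function(sys) {
    d <- arch[arch$system_name == sys, ]
    res <- tryCatch(
      phylum_contrasts(d$present, d$phylum,
        min_n = config$min_phylum_n, alpha = config$alpha
      ),
      error = function(e) {
        warning(sprintf("phylum contrasts skipped for %s: %s", sys, conditionMessage(e)),
          call. = FALSE
        )
        NULL
      }
    )
    if (is.null(res)) NULL else dplyr::mutate(tibble::as_tibble(res), system_name = sys, .before = 1)
  }))
  readr::write_tsv(contrasts, file.path(sdir, "phylum_contrasts.tsv"))

  # completeness-adjusted prevalence per system
  adj <- purrr::list_rbind(purrr::map(unique(dat$system_name), function(sys) {
    d <- dat[dat$system_name == sys, ]
    res <- tryCatch(
      completeness_adjusted_prevalence(d$present, d$completeness, d$domain),
      error = function(e) {
        warning(sprintf("completeness model skipped for %s: %s", sys, conditionMessage(e)),
          call. = FALSE
        )
        NULL
      }
    )
    if (is.null(res)) NULL else dplyr::mutate(tibble::as_tibble(res), system_name = sys, .before = 1)
  }))
  readr::write_tsv(adj, file.path(sdir, "completeness_adjusted_prevalence.tsv"))

  # count models (Archaea): NB-GLM on OGT, hurdle NB, per-predictor pseudo-R2
  archc <- cohort[cohort$domain == "Archaea", ]
  count_summaries <- list()
  nbfit <- tryCatch(nb_glm(archc$total_systems, data.frame(ogt_c = archc$ogt_c)),
    error = function(e) NULL
  )
  if (!is.null(nbfit)) {
    count_summaries$nb_ogt <- list(
      coefficients = as.list(nbfit$coefficients),
      theta = nbfit$theta,
      percent_change_per_10c = percent_change(nbfit, "ogt_c", delta = 10),
      pseudo_r2 = nagelkerke_r2_nb(nbfit)
    )
  }
  hfit <- tryCatch(
    hurdle_nb(archc$total_systems, data.frame(ogt_c = archc$ogt_c)),
    error = function(e) {
      warning(sprintf("hurdle model skipped: %s", conditionMessage(e)), call. = FALSE)
      NULL
    }
  )
  if (!is.null(hfit)) {
    count_summaries$hurdle_ogt <- list(
      zero = as.list(hfit$zero_part$coefficients),
      count = as.list(hfit$count_part$coefficients),
      theta = hfit$count_part$theta, loglik = hfit$loglik
    )
  }
  predictors <- list(
    log_size = data.frame(log_size = log(archc$size_mb)),
    phylum = data.frame(phylum = archc$phylum),
    completeness = data.frame(completeness = archc$completeness),
    ogt = data.frame(ogt_c = archc$ogt_c)
  )
  r2_tab <- purrr::imap(predictors, function(d, nm) {
    f <- tryCatch(nb_glm(archc$total_systems, d), error = function(e) NULL)
    if (is.null(f)) NULL else tibble::tibble(predictor = nm, pseudo_r2 = nagelkerke_r2_nb(f))
  })
  full_fit <- tryCatch(
    nb_glm(archc$total_systems, data.frame(
      log_size = log(archc$size_mb), phylum = archc$phylum,
      completeness = archc$completeness, ogt_c = archc$ogt_c
    )),
    error = function(e) NULL
  )
  if (!is.null(full_fit)) {
    r2_tab$full <- tibble::tibble(predictor = "full", pseudo_r2 = nagelkerke_r2_nb(full_fit))
  }
  r2_tab <- purrr::list_rbind(purrr::compact(unname(r2_tab)))
  readr::write_tsv(r2_tab, file.path(sdir, "pseudo_r2_by_predictor.tsv"))

  # genome size vs counts across domains
  sizestats <- tryCatch(
    {
      sr <- spearman_rho(cohort$size_mb, cohort$total_systems)
      reg <- size_regression_residual_test(
        cohort$total_systems, cohort$size_mb, cohort$domain
      )
      vp <- varpart_two(
        cohort$total_systems, log(cohort$size_mb),
        data.frame(domain = cohort$domain)
      )
      list(
        spearman_rho = sr$rho, spearman_p = sr$p_value,
        size_r2 = reg$r2, residual_test_p = reg$residual_test_p,
        varpart = as.list(vp)
      )
    },
    error = function(e) {
      warning(sprintf("size analysis skipped: %s", conditionMessage(e)), call. = FALSE)
      NULL
    }
  )

  # OGT thermal categories (Archaea)
  ogt_stats <- tryCatch(
    {
      kd <- kruskal_dunn(archc$total_systems, bin_ogt(archc$ogt_c))
      list(
        omnibus_p = kd$omnibus_p,
        pairwise = purrr::pmap(kd$pairwise, function(group1, group2, z, p_raw, p_adjusted) {
          list(
            group1 = group1, group2 = group2, z = z,
            p_raw = p_raw, p_adjusted = p_adjusted
          )
        })
      )
    },
    error = function(e) {
      warning(sprintf("OGT bin analysis skipped: %s", conditionMessage(e)), call. = FALSE)
      NULL
    }
  )

  report <- list(
    config_hash = config_hash(config),
    count_models = count_summaries,
    size_analysis = sizestats,
    ogt_bins = ogt_stats
  )
  jsonlite::write_json(report, file.path(sdir, "stats_report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  stage_log("stats", t0)
  invisible(list(
    prevalence_full = prev_full, prevalence_hq = prev_hq,
    contrasts = contrasts, completeness_adjusted = adj,
    count_models = count_summaries, pseudo_r2 = r2_tab,
    size_analysis = sizestats, ogt_bins = ogt_stats
  ))
}

#' Run the full pipeline
#'
#' [run_simulate()], [run_detect()], [run_stats()] in sequence on one
#' config. Bit-reproducible for a fixed (config, seed); timestamps appear
#' only in log messages.
#'
#' @param config A `defensome_config`.
#' @return Invisibly, a list with each stage's return value.
#' @export
run_all <- function(config = defensome_config()) {
  sim <- run_simulate(config)
  det <- run_detect(config)
  sta <- run_stats(config)
  invisible(list(simulate = sim, detect = det, stats = sta))
}
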