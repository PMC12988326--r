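test_that("reference catalogue covers every valid (type, role) combination and is deterministic", {
  refdb <- generate_reference_db(1, mean_len = 100, seed = 1)
  combos <- rm_role_table()
  expect_setequal(
    paste(refdb$rm_type, refdb$role),
    paste(combos$rm_type, combos$role)
  )
  # role constraints hold
  expect_true(all(refdb$role != "S" | refdb$rm_type == "I"))
  expect_true(all(refdb$role != "module" | refdb$rm_type %in% c("IV", "IIG")))
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", refdb$sequence)))
  # byte-identical FASTA for a repeated seed
  f1 <- tempfile(fileext = ".faa")
  f2 <- tempfile(fileext = ".faa")
  write_reference_fasta(generate_reference_db(2, 90, seed = 7), f1)
  write_reference_fasta(generate_reference_db(2, 90, seed = 7), f2)
  expect_identical(readLines(f1), readLines(f2))
  # round trip preserves metadata
  back <- read_reference_fasta(f1)
  expect_equal(back, generate_reference_db(2, 90, seed = 7))
  expect_error(generate_reference_db(0), class = "defensome_argument_error")
  expect_error(generate_reference_db(1, mean_len = 10), class = "defensome_argument_error")
})

test_that("mutate_to_identity hits the target identity exactly at round numbers", {
  s <- paste(rep(defensome:::AA_ALPHABET20, 5), collapse = "")
  expect_identical(mutate_to_identity(s, 1.0, seed = 99), s)
  m <- mutate_to_identity(s, 0.70, seed = 3)
  expect_equal(nchar(m), nchar(s))
  matches <- sum(strsplit(s, "")[[1]] == strsplit(m, "")[[1]])
  expect_equal(matches, 70)
  # generic targets stay within 1/len
  for (t in c(0.5, 0.64, 0.66, 0.95)) {
    m <- mutate_to_identity(s, t, seed = 5)
    frac <- mean(strsplit(s, "")[[1]] == strsplit(m, "")[[1]])
    expect_lte(abs(frac - t), 1 / nchar(s) + 1e-12)
  }
  expect_error(mutate_to_identity(s, 0), class = "defensome_argument_error")
  expect_error(mutate_to_identity("", 0.5), class = "defensome_argument_error")
})

test_that("generated genomes have ordered non-overlapping coordinates and recorded truth", {
  refdb <- tiny_refdb()
  g <- tiny_genome(rm_types = c("I", "II", "III", "IV", "IIG"), refdb = refdb)
  genes <- g$genes
  expect_true(all(diff(genes$start) > 0))
  expect_true(all(genes$start <= genes$end))
  expect_true(all(genes$start[-1] > genes$end[-nrow(genes)]))
  expect_true(all(genes$gene_index == seq_len(nrow(genes))))
  # every planted gene index exists in the genome
  expect_true(all(unlist(g$truth$gene_indices) %in% genes$gene_index))
  # operon components sit within an 11-gene window
  spans <- purrr::map_int(g$truth$gene_indices, ~ diff(range(.x)) + 1L)
  expect_true(all(spans <= 11L))
  # identical seeds give byte-identical FASTA + GFF3
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  write_genome(tiny_genome(seed = 8, refdb = refdb), d1)
  write_genome(tiny_genome(seed = 8, refdb = refdb), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("genome FASTA/GFF3 round trip preserves genes and order", {
  refdb <- tiny_refdb()
  g <- tiny_genome(rm_types = c("I", "IIG"), refdb = refdb, seed = 21)
  d <- tempfile()
  paths <- write_genome(g, d)
  back <- read_genome(paths["fasta"], paths["gff"])
  expect_equal(back$genes$gene_id, g$genes$gene_id)
  expect_equal(back$genes$sequence, g$genes$sequence)
  expect_equal(back$genes$start, g$genes$start)
})

test_that("interspersed decoys keep operons within the detection window", {
  refdb <- tiny_refdb()
  plan <- plan_genome("gI",
    systems = tibble::tibble(system_name = "RM_type_I", rm_type = "I"),
    intersperse = 2, identity = 0.9
  )
  g <- generate_genome(plan, refdb, seed = 4)
  span <- diff(range(unlist(g$truth$gene_indices))) + 1L
  expect_lte(span, 11L)
  expect_gte(span, 5L) # 3 components + 2 x 2 decoys
  calls <- call_rm_systems(g, truth_assignments(g))
  expect_equal(calls$rm_type, "I")
})

test_that("gene dropout retains a binomially plausible count and is deterministic", {
  refdb <- tiny_refdb()
  plan <- plan_genome("gD", n_decoys = 1000L)
  g <- generate_genome(plan, refdb, seed = 2)
  expect_identical(apply_incompleteness(g, 1.0, seed = 5), g)
  half <- apply_incompleteness(g, 0.5, seed = 5)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(nrow(half$genes), bounds[1])
  expect_lte(nrow(half$genes), bounds[2])
  # survivors keep their coordinates
  expect_true(all(half$genes$gene_id %in% g$genes$gene_id))
  merged <- merge(half$genes, g$genes, by = "gene_id")
  expect_equal(merged$start.x, merged$start.y)
  expect_identical(
    apply_incompleteness(g, 0.5, seed = 5)$genes,
    half$genes
  )
  expect_error(apply_incompleteness(g, 0), class = "defensome_argument_error")
  expect_error(apply_incompleteness(g, 1.2), class = "defensome_argument_error")
})

test_that("emitted tool calls carry planted non-RM systems, decoys, and a weak RM subset", {
  refdb <- tiny_refdb()
  plan <- plan_genome("gE",
    systems = tibble::tibble(
      system_name = c("CBASS", "CBASS", "RM_type_II"),
      rm_type = c(NA, NA, "II")
    ),
    n_dms = 1, n_vspr = 1, tool_rm_fraction = 1
  )
  g <- generate_genome(plan, refdb, seed = 6)
  calls <- emit_tool_calls(g, plan, seed = 9)
  expect_equal(sum(calls$system_name == "CBASS"), 2)
  expect_equal(sum(calls$system_name == "DMS"), 1)
  expect_equal(sum(calls$system_name == "VSPR"), 1)
  expect_equal(sum(calls$system_name == "RM_type_II"), 1)
  # filter_noncanonical drops exactly the decoys
  kept <- filter_noncanonical(calls)
  expect_setequal(unique(kept$system_name), c("CBASS", "RM_type_II"))
  # no planted systems -> empty table with the right columns
  plan0 <- plan_genome("g0")
  g0 <- generate_genome(plan0, refdb, seed = 1)
  empty <- emit_tool_calls(g0, plan0)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("genome_id", "system_name", "subtype", "gene_ids", "source"))
})

test_that("cohort generator recovers its planted coefficients and moments", {
  cfg <- cohort_config(n_per_domain = 3000)
  sim <- generate_cohort(cfg, seed = 11)
  expect_identical(sim$cohort, generate_cohort(cfg, seed = 11)$cohort)
  expect_true(all(sim$cohort$completeness > 0 & sim$cohort$completeness <= 1))
  # NB moment check: var ~ mean + mean^2/theta within groups of similar mean
  arch <- sim$cohort[sim$cohort$domain == "Archaea", ]
  fit <- nb_glm(arch$total_systems, data.frame(
    ogt_c = arch$ogt_c, log_size = log(arch$size_mb), phylum = arch$phylum
  ))
  expect_equal(unname(fit$coefficients["ogt_c"]), log(1.357) / 10, tolerance = 0.15)
  expect_equal(fit$theta, cfg$count_model$theta, tolerance = 0.25)
  # intercept-only NB mean identity
  cfg0 <- cohort_config(
    n_per_domain = 4000,
    count_model = list(intercept = log(5), beta_ogt = 0, beta_log_size = 0, beta_domain = 0),
    phyla = dplyr::mutate(cohort_config()$phyla, count_offset = 0)
  )
  sim0 <- generate_cohort(cfg0, seed = 2)
  expect_equal(mean(sim0$cohort$total_systems), 5, tolerance = 0.05)
  expect_error(
    cohort_config(count_model = list(theta = -1)),
    class = "defensome_argument_error"
  )
})
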