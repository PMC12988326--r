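test_that("conflict filtering removes assignments claimed by non-RM systems only", {
  asg <- tibble::tibble(
    query_id = c("g1|c1|1", "g1|c1|2", "g1|c1|3"),
    ref_id = "I-M-01", rm_type = "I", role = "M",
    identity = 0.9, coverage = 1
  )
  ext <- tibble::tibble(
    genome_id = "g1",
    system_name = c("CBASS", "RM_type_II"),
    subtype = NA_character_,
    gene_ids = c("g1|c1|1", "g1|c1|2"),
    source = "padloc"
  )
  out <- filter_conflicts(asg, ext)
  # CBASS claims gene 1 (dropped); the RM call claims gene 2 (kept)
  expect_setequal(out$query_id, c("g1|c1|2", "g1|c1|3"))
  expect_identical(filter_conflicts(asg, ext[0, ]), asg)
  expect_identical(filter_conflicts(asg, NULL), asg)
})

test_that("neighborhood extraction honors the window and contig ends", {
  genes <- tibble::tibble(
    genome_id = "g1", contig = "c1", gene_index = 1:30,
    gene_id = paste0("g1|c1|", 1:30),
    start = (1:30) * 1000, end = (1:30) * 1000 + 500,
    strand = "+", sequence = "M"
  )
  g <- structure(list(genes = genes, truth = tibble::tibble()),
    class = "annotated_genome"
  )
  nb <- extract_neighborhood(g, "g1|c1|11", window = 5)
  expect_equal(nb$gene_index, 6:16)
  expect_equal(sum(nb$is_anchor), 1)
  # truncation at the left end
  nb1 <- extract_neighborhood(g, "g1|c1|1", window = 5)
  expect_equal(nb1$gene_index, 1:6)
  # short contig returns everything
  g3 <- structure(
    list(genes = genes[1:3, ], truth = tibble::tibble()),
    class = "annotated_genome"
  )
  expect_equal(nrow(extract_neighborhood(g3, "g1|c1|2", window = 5)), 3)
  expect_error(extract_neighborhood(g, "nope"), class = "defensome_lookup_error")
})

make_nb <- function(roles, types, anchor_at = 1) {
  n <- length(roles)
  tibble::tibble(
    genome_id = "g", contig = "c", gene_index = seq_len(n),
    gene_id = paste0("g|c|", seq_len(n)),
    start = seq_len(n) * 100, end = seq_len(n) * 100 + 50,
    strand = "+", sequence = "M",
    is_anchor = seq_len(n) == anchor_at,
    rm_type = types, role = roles
  )
}

test_that("per-type architecture rules classify neighborhoods", {
  # Type I needs R + M + S of type I
  expect_equal(
    classify_rm(make_nb(c("R", "M", "S"), c("I", "I", "I")))$rm_type, "I"
  )
  # missing S -> no call
  expect_true(is.na(
    classify_rm(make_nb(c("R", "M", NA), c("I", "I", NA)))$rm_type
  ))
  # Type II R+M
  expect_equal(
    classify_rm(make_nb(c("R", "M"), c("II", "II")))$rm_type, "II"
  )
  # cross-type components do not satisfy the rule
  expect_true(is.na(
    classify_rm(make_nb(c("R", "M"), c("II", "III")))$rm_type
  ))
  # Type III R+M
  expect_equal(
    classify_rm(make_nb(c("R", "M"), c("III", "III")))$rm_type, "III"
  )
  # IIG / IV modules alone
  expect_equal(classify_rm(make_nb("module", "IIG"))$rm_type, "IIG")
  expect_equal(classify_rm(make_nb("module", "IV"))$rm_type, "IV")
  # an M anchor is rejected
  expect_error(
    classify_rm(make_nb(c("M", "R"), c("II", "II"))),
    class = "defensome_argument_error"
  )
  # nearest eligible component wins; ties go upstream
  nb <- make_nb(c("M", "R", "M"), c("II", "II", "II"), anchor_at = 2)
  expect_equal(classify_rm(nb)$component_gene_ids, c("g|c|2", "g|c|1"))
})

test_that("call_rm_systems recovers one planted operon of each type exactly once", {
  refdb <- tiny_refdb()
  g <- tiny_genome(
    rm_types = c("I", "II", "III", "IV", "IIG"),
    identity = 0.8, seed = 31, refdb = refdb
  )
  calls <- call_rm_systems(g, truth_assignments(g))
  expect_setequal(calls$rm_type, c("I", "II", "III", "IV", "IIG"))
  expect_equal(nrow(calls), 5)
  # disjoint component sets
  comp <- unlist(calls$component_gene_ids)
  expect_equal(anyDuplicated(comp), 0)
  # decoy-only genome yields no calls
  g0 <- generate_genome(plan_genome("g0", n_decoys = 20), refdb, seed = 2)
  expect_equal(nrow(call_rm_systems(g0, truth_assignments(g)[0, ])), 0)
})

test_that("a lone II-R gene and incomplete operons produce no call", {
  refdb <- tiny_refdb()
  plan <- plan_genome("gL",
    systems = tibble::tibble(
      system_name = "RM_type_II", rm_type = "II", n_genes = NA, roles = list("R")
    )
  )
  g <- generate_genome(plan, refdb, seed = 3)
  calls <- call_rm_systems(g, truth_assignments(g))
  expect_equal(nrow(calls), 0)
})

test_that("a shared component is consumed by the left anchor only", {
  # two II-R anchors flanking a single II-M
  genes <- tibble::tibble(
    genome_id = "g", contig = "c", gene_index = 1:3,
    gene_id = paste0("g|c|", 1:3),
    start = c(100, 300, 500), end = c(200, 400, 600),
    strand = "+", sequence = "M"
  )
  g <- structure(list(genes = genes, truth = tibble::tibble()),
    class = "annotated_genome"
  )
  asg <- tibble::tibble(
    query_id = genes$gene_id,
    ref_id = c("II-R-01", "II-M-01", "II-R-01"),
    rm_type = "II", role = c("R", "M", "R"),
    identity = 0.9, coverage = 1
  )
  calls <- call_rm_systems(g, asg)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$anchor_gene_id, "g|c|1")
  expect_setequal(calls$component_gene_ids[[1]], c("g|c|1", "g|c|2"))
})

test_that("calls are invariant under contig reversal up to anchor relabeling", {
  refdb <- tiny_refdb()
  g <- tiny_genome(
    rm_types = c("I", "II", "IIG"), identity = 0.8,
    seed = 17, refdb = refdb
  )
  rev_genes <- g$genes[rev(seq_len(nrow(g$genes))), ]
  total <- max(g$genes$end) + 100
  rev_genes <- rev_genes |>
    dplyr::mutate(
      new_start = total - .data$end, new_end = total - .data$start,
      start = .data$new_start, end = .data$new_end,
      gene_index = dplyr::row_number()
    ) |>
    dplyr::select(-"new_start", -"new_end")
  g_rev <- structure(list(genes = rev_genes, truth = g$truth),
    class = "annotated_genome"
  )
  asg <- truth_assignments(g)
  fwd <- call_rm_systems(g, asg)
  bwd <- call_rm_systems(g_rev, asg)
  expect_equal(sort(fwd$rm_type), sort(bwd$rm_type))
  expect_setequal(
    purrr::map_chr(fwd$component_gene_ids, ~ paste(sort(.x), collapse = "+")),
    purrr::map_chr(bwd$component_gene_ids, ~ paste(sort(.x), collapse = "+"))
  )
})

test_that("recall degrades monotonically with completeness in simulation", {
  refdb <- tiny_refdb()
  recalls <- purrr::map_dbl(c(1, 0.7, 0.4), function(comp) {
    co <- simulate_rm_cohort(25, refdb,
      rm_types = c("I", "II"), identity = 0.8,
      completeness = comp, seed = 5
    )
    calls <- purrr::list_rbind(purrr::map(co$genomes, function(g) {
      call_rm_systems(g, truth_assignments(g))
    }))
    rm_precision_recall(calls, co$truth)$recall
  })
  expect_equal(recalls[1], 1)
  expect_true(all(diff(recalls) < 0))
})
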