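#' Drop non-defense annotation rows from a call table
#'
#' Removes rows whose `system_name` is (case-insensitively) `DMS` (DNA
#' modification proteins that do not form complete defense systems) or
#' `VSPR` (entries that are not defense systems). All other rows are kept
#' in their original order; the operation is idempotent.
#'
#' @param calls Defense call tibble.
#' @return The filtered tibble.
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   genome_id = "g1",
#'   system_name = c("CBASS", "DMS", "VSPR", "viperin"),
#'   subtype = NA, gene_ids = NA, source = "padloc"
#' )
#' filter_noncanonical(calls)$system_name
filter_noncanonical <- function(calls) {
  calls[!toupper(calls$system_name) %in% NONCANONICAL_SYSTEMS, ]
}

#' Merge external tool calls with homology-based RM calls
#'
#' For genomes on the REBASE path (all by default), tool rows naming an RM
#' system are dropped and replaced by the homology-based `rebase_rm` calls;
#' non-RM tool rows pass through untouched. Genomes not on the REBASE path
#' keep their tool RM rows verbatim and contribute no `rebase_rm` rows.
#'
#' @param tool_calls External defense call tibble.
#' @param rm_calls RM call tibble from [call_rm_systems()].
#' @param rebase_genomes Character vector of genome ids using the REBASE
#'   path, or `NULL` (default) for all genomes.
#' @param rm_name_pattern Regular expression marking tool RM rows.
#' @return Combined call tibble with columns `genome_id`, `system_name`,
#'   `subtype`, `gene_ids`, `source`.
#' @export
merge_defensome <- function(tool_calls, rm_calls, rebase_genomes = NULL,
                            rm_name_pattern = DEFAULT_RM_NAMES) {
  on_rebase <- function(gid) {
    if (is.null(rebase_genomes)) rep(TRUE, length(gid)) else gid %in% rebase_genomes
  }
  kept_tool <- tool_calls[
    !(is_rm_name(tool_calls$system_name, rm_name_pattern) &
      on_rebase(tool_calls$genome_id)),
  ]
  if (nrow(rm_calls) > 0) {
    rm_rows <- rm_calls[on_rebase(rm_calls$genome_id), ]
    rm_tbl <- tibble::tibble(
      genome_id = rm_rows$genome_id,
      system_name = "RM",
      subtype = rm_rows$rm_type,
      gene_ids = purrr::map_chr(rm_rows$component_gene_ids, paste, collapse = ";"),
      source = "rebase_rm"
    )
  } else {
    rm_tbl <- tool_calls[0, ]
  }
  dplyr::bind_rows(kept_tool, rm_tbl)
}

#' Summarize a call table into a per-genome cohort table
#'
#' Counts calls per (genome, system), plus `total_systems` (all occurrences)
#' and `distinct_types` (systems with count > 0). Genomes present in
#' `metadata` but without calls get zero rows, so prevalence denominators
#' are cohort-wide.
#'
#' @param calls Defense call tibble (already filtered/merged).
#' @param metadata Tibble with one row per genome: `genome_id`, `domain`,
#'   `phylum`, `size_mb`, `completeness`, `ogt_c` (extra columns pass
#'   through).
#' @return A cohort tibble: metadata columns, `total_systems`,
#'   `distinct_types`, and one count column per system name.
#' @export
summarize_cohort <- function(calls, metadata) {
  metadata <- tibble::as_tibble(metadata)
  unknown <- setdiff(unique(calls$genome_id), metadata$genome_id)
  if (length(unknown) > 0) {
    abort(sprintf(
      "calls reference genomes absent from metadata: %s",
      paste(head(unknown, 3), collapse = ", ")
    ), class = "defensome_reference_error")
  }
  counts <- calls |>
    dplyr::count(.data$genome_id, .data$system_name) |>
    tidyr::pivot_wider(
      names_from = "system_name", values_from = "n", values_fill = 0L
    )
  out <- metadata |>
    dplyr::left_join(counts, by = "genome_id")
  sys_cols <- setdiff(names(out), names(metadata))
  out <- out |>
    dplyr::mutate(dplyr::across(dplyr::all_of(sys_cols), ~ dplyr::coalesce(.x, 0L)))
  sys_mat <- as.matrix(out[sys_cols])
  out$total_systems <- as.integer(rowSums(sys_mat))
  out$distinct_types <- as.integer(rowSums(sys_mat > 0))
  out |>
    dplyr::relocate("total_systems", "distinct_types", .after = dplyr::last_col()) |>
    dplyr::relocate(dplyr::all_of(sys_cols), .after = dplyr::last_col())
}

# System count columns of a cohort table (everything after the two totals).
cohort_system_columns <- function(cohort) {
  meta_cols <- c(
    "genome_id", "domain", "phylum", "size_mb", "completeness", "ogt_c",
    "total_systems", "distinct_types"
  )
  setdiff(names(cohort), meta_cols)
}

#' Per-domain prevalence of each system
#'
#' Prevalence is the fraction of genomes encoding the system at least once
#' (multiple copies count once); abundance sums all occurrences.
#'
#' @param cohort Cohort tibble from [summarize_cohort()].
#' @return Tibble: `domain`, `system_name`, `n_genomes`, `n_present`,
#'   `prevalence`, `total_count`.
#' @export
system_prevalence <- function(cohort) {
  sys_cols <- cohort_system_columns(cohort)
  cohort |>
    tidyr::pivot_longer(dplyr::all_of(sys_cols),
      names_to = "system_name", values_to = "count"
    ) |>
    dplyr::group_by(.data$domain, .data$system_name) |>
    dplyr::summarise(
      n_genomes = dplyr::n(),
      n_present = sum(.data$count > 0),
      prevalence = mean(.data$count > 0),
      total_count = sum(.data$count),
      .groups = "drop"
    )
}

#' The core defensome: top-k most prevalent systems per domain
#'
#' Ranks systems within each domain by prevalence (fraction of genomes with
#' the system), breaking ties by higher total occurrence count, then by
#' name; returns the per-domain top-k lists and their union.
#'
#' @param cohort Cohort tibble (must contain both domains).
#' @param k Systems retained per domain (default 20).
#' @return A list with `per_domain` (tibble: domain, rank, system_name,
#'   prevalence) and `union` (character vector of distinct system names).
#' @export
core_defensome <- function(cohort, k = 20L) {
  assert_scalar_number(k, "k", min = 1)
  prev <- system_prevalence(cohort)
  per_domain <- prev |>
    dplyr::group_by(.data$domain) |>
    dplyr::arrange(
      dplyr::desc(.data$prevalence), dplyr::desc(.data$total_count),
      .data$system_name,
      .by_group = TRUE
    ) |>
    dplyr::slice_head(n = as.integer(k)) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("domain", "rank", "system_name", "prevalence")
  list(per_domain = per_domain, union = unique(per_domain$system_name))
}

#' Fraction of genomes with no defenses beyond an excluded core
#'
#' Flags genomes whose every called system is in `exclude` (RM families and
#' CRISPR-Cas by default) or that have no calls at all, and reports the
#' flagged fraction per domain and per phylum.
#'
#' @param cohort Cohort tibble.
#' @param exclude Character vector of system names not counted as
#'   "additional" defenses; names matching the RM pattern are always
#'   excluded.
#' @param rm_name_pattern Regular expression marking RM system names.
#' @return Tibble: `domain`, `phylum` (`NA` for domain-level rows),
#'   `n_genomes`, `fraction_defenseless`.
#' @export
defenseless_fraction <- function(cohort, exclude = c("RM", "CRISPR-Cas"),
                                 rm_name_pattern = DEFAULT_RM_NAMES) {
  sys_cols <- cohort_system_columns(cohort)
  if (nrow(cohort) == 0) {
    return(tibble::tibble(
      domain = character(), phylum = character(),
      n_genomes = integer(), fraction_defenseless = numeric()
    ))
  }
  core <- sys_cols[sys_cols %in% exclude | is_rm_name(sys_cols, rm_name_pattern)]
  beyond <- setdiff(sys_cols, core)
  flag <- if (length(beyond) == 0) {
    rep(TRUE, nrow(cohort))
  } else {
    rowSums(as.matrix(cohort[beyond])) == 0
  }
  by_domain <- cohort |>
    dplyr::mutate(.flag = flag) |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(
      phylum = NA_character_, n_genomes = dplyr::n(),
      fraction_defenseless = mean(.data$.flag), .groups = "drop"
    )
  by_phylum <- cohort |>
    dplyr::mutate(.flag = flag) |>
    dplyr::group_by(.data$domain, .data$phylum) |>
    dplyr::summarise(
      n_genomes = dplyr::n(),
      fraction_defenseless = mean(.data$.flag), .groups = "drop"
    )
  dplyr::bind_rows(by_domain, by_phylum)
}

#' Defense system density per megabase
#'
#' @param cohort Cohort tibble with positive `size_mb`.
#' @return The cohort with a `systems_per_mb` column.
#' @export
normalize_per_mb <- function(cohort) {
  if (any(!is.finite(cohort$size_mb)) || any(cohort$size_mb <= 0)) {
    abort("`size_mb` must be positive and finite for every genome.",
      class = "defensome_argument_error"
    )
  }
  dplyr::mutate(cohort, systems_per_mb = .data$total_systems / .data$size_mb)
}
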