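# Default system-name patterns treated as RM rows in external call tables.
DEFAULT_RM_NAMES <- "^(RM($|_)|RM_type|Type[_ ]?(I|II|III|IV|IIG)[_ ]?RM)"

# TRUE for system names that denote restriction-modification systems.
is_rm_name <- function(system_name, rm_name_pattern = DEFAULT_RM_NAMES) {
  grepl(rm_name_pattern, system_name, ignore.case = TRUE)
}

#' Remove homology assignments claimed by non-RM defense systems
#'
#' Proteins matched to the RM reference catalogue but identified as part of
#' a non-RM defense system by an external tool are conflicts: the external
#' architecture evidence wins and the RM assignment is dropped. Assignments
#' appearing in external RM calls are retained.
#'
#' @param assignments Assignment tibble from [best_hit_assign()].
#' @param external_calls Defense call tibble (may be empty).
#' @param rm_name_pattern Regular expression marking RM system names.
#' @return The filtered assignment tibble.
#' @export
filter_conflicts <- function(assignments, external_calls,
                             rm_name_pattern = DEFAULT_RM_NAMES) {
  if (is.null(external_calls) || nrow(external_calls) == 0) {
    return(assignments)
  }
  non_rm <- external_calls[!is_rm_name(external_calls$system_name, rm_name_pattern), ]
  claimed <- unique(unlist(strsplit(non_rm$gene_ids[!is.na(non_rm$gene_ids)], ";",
    fixed = TRUE
  )))
  assignments[!assignments$query_id %in% claimed, ]
}

#' Extract the gene neighborhood around an anchor
#'
#' Returns up to `2 * window + 1` genes in rank order on the anchor's
#' contig — `window` genes upstream and `window` downstream — truncated at
#' contig ends. Contigs are treated as linear.
#'
#' @param genome An `annotated_genome`.
#' @param anchor_gene_id Gene id of the anchor.
#' @param window Genes captured on each side (default 5).
#' @return A tibble of the neighborhood genes with an `is_anchor` column.
#' @export
extract_neighborhood <- function(genome, anchor_gene_id, window = 5L) {
  stopifnot(inherits(genome, "annotated_genome"))
  assert_scalar_number(window, "window", min = 1)
  genes <- genome$genes
  pos <- which(genes$gene_id == anchor_gene_id)
  if (length(pos) != 1L) {
    abort(sprintf("anchor gene '%s' not found in genome.", anchor_gene_id),
      class = "defensome_lookup_error"
    )
  }
  contig <- genes$contig[pos]
  on_contig <- genes[genes$contig == contig, ]
  on_contig <- on_contig[order(on_contig$start), ]
  rank <- which(on_contig$gene_id == anchor_gene_id)
  idx <- seq(max(1L, rank - window), min(nrow(on_contig), rank + window))
  out <- on_contig[idx, ]
  out$is_anchor <- out$gene_id == anchor_gene_id
  out
}

#' Classify a neighborhood into an RM system type
#'
#' Architecture rules, with the anchor a restriction nuclease (role `R`) or
#' a single-protein module: Type I requires type-I `R`, `M` and `S` in the
#' neighborhood; Types II and III require the type-matched `R` and `M`;
#' Types IV and IIG are called from the module alone. Components are drawn
#' only from genes assigned to the anchor's own RM type.
#'
#' @param neighborhood Tibble from [extract_neighborhood()], annotated with
#'   `rm_type` and `role` columns (NA for unassigned genes).
#' @return A list with `rm_type` (type string or `NA` when no rule is
#'   satisfied) and `component_gene_ids` (anchor plus the nearest satisfying
#'   components; ties broken upstream).
#' @export
classify_rm <- function(neighborhood) {
  nb <- neighborhood
  anchor_row <- which(nb$is_anchor)
  stopifnot(length(anchor_row) == 1L)
  anchor_role <- nb$role[anchor_row]
  anchor_type <- nb$rm_type[anchor_row]
  if (is.na(anchor_role) || !anchor_role %in% c("R", "module")) {
    abort("anchor must be an assigned restriction nuclease (role R or module).",
      class = "defensome_argument_error"
    )
  }
  if (anchor_role == "module") {
    if (anchor_type %in% c("IV", "IIG")) {
      return(list(rm_type = anchor_type, component_gene_ids = nb$gene_id[anchor_row]))
    }
    return(list(rm_type = NA_character_, component_gene_ids = character()))
  }
  needed <- setdiff(rm_required_roles(anchor_type), "R")
  if (length(needed) == 0L || !anchor_type %in% c("I", "II", "III")) {
    return(list(rm_type = NA_character_, component_gene_ids = character()))
  }
  dist <- abs(seq_len(nrow(nb)) - anchor_row)
  comps <- purrr::map_chr(needed, function(role) {
    cand <- which(!is.na(nb$role) & nb$role == role &
      nb$rm_type == anchor_type & !nb$is_anchor)
    if (length(cand) == 0L) {
      return(NA_character_)
    }
    # nearest to the anchor; ties resolved upstream (smaller rank)
    cand <- cand[order(dist[cand], cand)]
    nb$gene_id[cand[1]]
  })
  if (anyNA(comps)) {
    return(list(rm_type = NA_character_, component_gene_ids = character()))
  }
  list(
    rm_type = anchor_type,
    component_gene_ids = c(nb$gene_id[anchor_row], comps)
  )
}

#' Call RM systems in a genome from homology assignments
#'
#' The full neighborhood pipeline: conflict-filter assignments against
#' external defense calls, enumerate anchor genes (assigned role `R` or
#' `module`) left to right by coordinate, extract each anchor's +/- `window`
#' gene neighborhood, apply the per-type architecture rules, and on success
#' emit a call consuming the anchor and its nearest satisfying components.
#' Consumed genes are unavailable to later anchors, so component sets of
#' distinct calls are disjoint and the procedure is deterministic.
#'
#' @param genome An `annotated_genome`.
#' @param assignments Assignment tibble from [best_hit_assign()].
#' @param external_calls Optional external defense call tibble for conflict
#'   filtering.
#' @param window Neighborhood half-width in genes (default 5).
#' @param rm_name_pattern Passed to [filter_conflicts()].
#' @return A tibble of RM system calls: `genome_id`, `rm_type`,
#'   `anchor_gene_id`, `component_gene_ids` (list-column), `source =
#'   "rebase_rm"`.
#' @export
call_rm_systems <- function(genome, assignments, external_calls = NULL,
                            window = 5L, rm_name_pattern = DEFAULT_RM_NAMES) {
  stopifnot(inherits(genome, "annotated_genome"))
  assignments <- filter_conflicts(assignments, external_calls, rm_name_pattern)
  genes <- genome$genes
  m <- match(genes$gene_id, assignments$query_id)
  ann <- genes
  ann$rm_type <- assignments$rm_type[m]
  ann$role <- assignments$role[m]
  anchors <- ann[!is.na(ann$role) & ann$role %in% c("R", "module"), ]
  anchors <- anchors[order(anchors$contig, anchors$start), ]

  consumed <- character()
  calls <- list()
  for (i in seq_len(nrow(anchors))) {
    anchor_id <- anchors$gene_id[i]
    if (anchor_id %in% consumed) next
    nb <- extract_neighborhood(genome, anchor_id, window = window)
    mi <- match(nb$gene_id, assignments$query_id)
    nb$rm_type <- assignments$rm_type[mi]
    nb$role <- assignments$role[mi]
    # consumed genes no longer count as available components
    nb$role[nb$gene_id %in% consumed] <- NA_character_
    nb$rm_type[nb$gene_id %in% consumed] <- NA_character_
    res <- classify_rm(nb)
    if (!is.na(res$rm_type)) {
      consumed <- c(consumed, res$component_gene_ids)
      calls <- c(calls, list(tibble::tibble(
        genome_id = genes$genome_id[1],
        rm_type = res$rm_type,
        anchor_gene_id = anchor_id,
        component_gene_ids = list(res$component_gene_ids),
        source = "rebase_rm"
      )))
    }
  }
  if (length(calls) == 0L) {
    return(tibble::tibble(
      genome_id = character(), rm_type = character(),
      anchor_gene_id = character(), component_gene_ids = list(),
      source = character()
    ))
  }
  purrr::list_rbind(calls)
}

#' Detect RM systems across a cohort of genomes
#'
#' Runs [compute_hits()] and [best_hit_assign()] on the pooled genes of the
#' whole cohort (gene ids are genome-qualified, so pooling is safe and far
#' faster than per-genome search), then [call_rm_systems()] per genome.
#'
#' @param genomes List of `annotated_genome` objects.
#' @param refdb Reference catalogue.
#' @param external_calls Optional combined external call tibble (matched to
#'   genomes by `genome_id`).
#' @param min_identity,min_coverage,window Pipeline thresholds.
#' @return Combined RM call tibble.
#' @export
detect_rm_cohort <- function(genomes, refdb, external_calls = NULL,
                             min_identity = 0.65, min_coverage = 0.8,
                             window = 5L) {
  all_genes <- purrr::list_rbind(purrr::map(genomes, "genes"))
  pooled <- structure(
    list(genes = all_genes, truth = tibble::tibble()),
    class = "annotated_genome"
  )
  hits <- compute_hits(pooled, refdb)
  asg <- best_hit_assign(hits, refdb,
    min_identity = min_identity, min_coverage = min_coverage
  )
  asg$.genome <- all_genes$genome_id[match(asg$query_id, all_genes$gene_id)]
  purrr::list_rbind(purrr::map(genomes, function(g) {
    gid <- g$genes$genome_id[1]
    ext <- external_calls
    if (!is.null(ext) && nrow(ext) > 0) {
      ext <- ext[ext$genome_id == gid, ]
    }
    call_rm_systems(g, asg[!is.na(asg$.genome) & asg$.genome == gid, ],
      ext,
      window = window
    )
  }))
}

#' Precision and recall of RM calls against planted ground truth
#'
#' A planted system counts as recovered when a call of the same `rm_type`
#' exists in the same genome (type-level evaluation); multiplicities are
#' respected by matching counts per (genome, type).
#'
#' @param calls RM call tibble.
#' @param truth Ground-truth tibble (from the simulator); only complete
#'   planted RM operons are expected to be called.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
rm_precision_recall <- function(calls, truth) {
  truth_rm <- truth |>
    dplyr::filter(!is.na(.data$rm_type), .data$complete) |>
    dplyr::count(.data$genome_id, .data$rm_type, name = "n_true")
  called <- calls |>
    dplyr::count(.data$genome_id, .data$rm_type, name = "n_called")
  joined <- dplyr::full_join(truth_rm, called, by = c("genome_id", "rm_type")) |>
    dplyr::mutate(
      n_true = dplyr::coalesce(.data$n_true, 0L),
      n_called = dplyr::coalesce(.data$n_called, 0L),
      tp = pmin(.data$n_true, .data$n_called)
    )
  tp <- sum(joined$tp)
  fp <- sum(joined$n_called) - tp
  fn <- sum(joined$n_true) - tp
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  )
}

#' Write RM calls and per-genome type counts as TSV
#'
#' @param calls RM call tibble.
#' @param path Calls TSV path (`component_gene_ids` semicolon-joined).
#' @param summary_path Optional per-genome per-type count TSV.
#' @return `path`, invisibly.
#' @export
write_rm_calls <- function(calls, path, summary_path = NULL) {
  flat <- calls |>
    dplyr::mutate(component_gene_ids = purrr::map_chr(
      .data$component_gene_ids, paste,
      collapse = ";"
    ))
  readr::write_tsv(flat, path)
  if (!is.null(summary_path)) {
    calls |>
      dplyr::count(.data$genome_id, .data$rm_type) |>
      tidyr::pivot_wider(
        names_from = "rm_type", values_from = "n", values_fill = 0L
      ) |>
      readr::write_tsv(summary_path)
  }
  invisible(path)
}
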