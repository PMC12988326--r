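#' Emulate external defense-annotation tool output for a genome
#'
#' Produces a Padloc-style call table: one row per planted non-RM system,
#' decoy rows labelled `DMS` and `VSPR` (annotation categories that are not
#' defense systems and must be filtered out downstream), and, optionally, RM
#' rows mimicking a weaker external tool that rediscovers only a subset of
#' the planted RM systems — exercising the policy of replacing tool RM rows
#' with homology-based RM calls.
#'
#' @param genome An `annotated_genome` carrying a ground-truth table.
#' @param plan Optional `genome_plan`; supplies `n_dms`, `n_vspr` and
#'   `tool_rm_fraction` (all default 0 when absent).
#' @param seed Integer seed (decoy gene ids and the tool-RM subset are
#'   sampled).
#' @return A tibble with columns `genome_id`, `system_name`, `subtype`,
#'   `gene_ids` (semicolon-joined), `source`.
#' @export
emit_tool_calls <- function(genome, plan = NULL, seed = 1L) {
  stopifnot(inherits(genome, "annotated_genome"))
  n_dms <- plan$n_dms %||% 0L
  n_vspr <- plan$n_vspr %||% 0L
  rm_frac <- plan$tool_rm_fraction %||% 0
  truth <- genome$truth
  gid <- genome$genes$genome_id[1] %||% (plan$genome_id %||% NA_character_)

  empty <- tibble::tibble(
    genome_id = character(), system_name = character(),
    subtype = character(), gene_ids = character(), source = character()
  )

  rows <- list(empty)
  if (nrow(truth) > 0) {
    non_rm <- truth[is.na(truth$rm_type), ]
    if (nrow(non_rm) > 0) {
      rows <- c(rows, list(tibble::tibble(
        genome_id = non_rm$genome_id,
        system_name = non_rm$system_name,
        subtype = NA_character_,
        gene_ids = purrr::map_chr(non_rm$gene_ids, paste, collapse = ";"),
        source = "padloc"
      )))
    }
  }
  with_seed(seed, {
    if (nrow(truth) > 0 && rm_frac > 0) {
      rm_truth <- truth[!is.na(truth$rm_type), ]
      n_take <- floor(rm_frac * nrow(rm_truth))
      if (n_take > 0) {
        take <- rm_truth[sort(sample.int(nrow(rm_truth), n_take)), ]
        rows <- c(rows, list(tibble::tibble(
          genome_id = take$genome_id,
          system_name = paste0("RM_type_", take$rm_type),
          subtype = take$rm_type,
          gene_ids = purrr::map_chr(take$gene_ids, paste, collapse = ";"),
          source = "padloc"
        )))
      }
    }
    n_decoy <- n_dms + n_vspr
    if (n_decoy > 0) {
      # Decoy rows point at random non-planted genes.
      planted <- unlist(truth$gene_ids %||% list(character()))
      pool <- setdiff(genome$genes$gene_id, planted)
      ids <- sample(pool, min(n_decoy, length(pool)))
      ids <- rep_len(ids, n_decoy)
      rows <- c(rows, list(tibble::tibble(
        genome_id = gid,
        system_name = rep(c("DMS", "VSPR"), c(n_dms, n_vspr)),
        subtype = NA_character_,
        gene_ids = ids,
        source = "padloc"
      )))
    }
  })
  purrr::list_rbind(rows)
}

#' Read / write Padloc-style defense call tables
#'
#' The on-disk dialect is a CSV with columns `system`, `target.name`
#' (genome id), `subtype`, `protein.ids` (semicolon-joined) and `source`;
#' readers map these onto the package's call-table columns.
#'
#' @param calls Call tibble (as from [emit_tool_calls()]).
#' @param path File path.
#' @return `write_call_table()` returns `path` invisibly;
#'   `read_call_table()` returns the call tibble.
#' @export
write_call_table <- function(calls, path) {
  out <- tibble::tibble(
    system = calls$system_name,
    target.name = calls$genome_id,
    subtype = calls$subtype,
    protein.ids = calls$gene_ids,
    source = calls$source
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_call_table
#' @export
read_call_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  need <- c("system", "target.name")
  if (!all(need %in% names(raw))) {
    abort(sprintf(
      "call table %s lacks required columns: %s", path,
      paste(setdiff(need, names(raw)), collapse = ", ")
    ), class = "defensome_format_error")
  }
  tibble::tibble(
    genome_id = as.character(raw$target.name),
    system_name = as.character(raw$system),
    subtype = as.character(raw$subtype %||% NA_character_),
    gene_ids = as.character(raw$protein.ids %||% NA_character_),
    source = as.character(raw$source %||% "padloc")
  )
}
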