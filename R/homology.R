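#' Pairwise protein alignment with identity and coverage statistics
#'
#' Needleman-Wunsch alignment with affine gaps (BLOSUM62, gap open 11, gap
#' extension 1) and free end gaps (overlap alignment), so unaligned
#' overhangs are terminal gaps rather than being smeared into internal
#' gaps. Identity is matches / alignment columns excluding terminal gaps,
#' approximating the identity a local search tool reports; coverages are
#' the aligned span over each sequence's full length.
#'
#' @param query,target Non-empty amino-acid strings. `query` may be a
#'   character vector; the single `target` is aligned against each element.
#' @param query_id,ref_id Optional identifiers carried into the result.
#' @return A tibble of hits: `query_id`, `ref_id`, `identity`,
#'   `query_coverage`, `target_coverage`, `score`, `evalue` (always `NA`;
#'   the internal aligner does not compute database e-values).
#' @export
#' @examples
#' align_identity("MKVLAGRSTW", "MKVLAGRSTW")
align_identity <- function(query, target, query_id = NULL, ref_id = NULL) {
  if (!is.character(query) || length(query) < 1L || any(nchar(query) == 0L)) {
    abort("`query` must be one or more non-empty strings.",
      class = "defensome_argument_error"
    )
  }
  if (!is.character(target) || length(target) != 1L || nchar(target) == 0L) {
    abort("`target` must be a single non-empty string.",
      class = "defensome_argument_error"
    )
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(query),
    subject = Biostrings::AAString(target),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1, type = "overlap"
  )
  # pattern()/subject() return the gapped strings over the aligned region,
  # i.e. with terminal gaps already clipped
  pat <- as.character(Biostrings::pattern(aln))
  sub <- as.character(Biostrings::subject(aln))
  stats <- purrr::pmap(
    list(pat, sub, nchar(query)),
    function(p, s, qlen) alignment_stats(p, s, qlen, nchar(target))
  )
  tibble::tibble(
    query_id = query_id %||% paste0("q", seq_along(query)),
    ref_id = ref_id %||% "target",
    identity = purrr::map_dbl(stats, "identity"),
    query_coverage = purrr::map_dbl(stats, "qcov"),
    target_coverage = purrr::map_dbl(stats, "tcov"),
    score = Biostrings::score(aln),
    evalue = NA_real_
  )
}

# Identity / coverage from the gapped strings of the aligned region
# (terminal gaps clipped) plus the full sequence lengths.
alignment_stats <- function(pat, sub, qlen, tlen) {
  p <- strsplit(pat, "", fixed = TRUE)[[1]]
  s <- strsplit(sub, "", fixed = TRUE)[[1]]
  list(
    identity = sum(p == s & p != "-") / length(p),
    qcov = sum(p != "-") / qlen,
    tcov = sum(s != "-") / tlen
  )
}

#' Compute a hit table for a genome against a reference catalogue
#'
#' Aligns genes of `genome` against entries of `refdb` with
#' [align_identity()]. A desk-scale stand-in for an external protein search:
#' like such tools, it screens pairs with a shared k-mer prefilter and only
#' aligns pairs whose distinct shared k-mer fraction reaches
#' `min_kmer_share` (random unrelated proteins share essentially none;
#' homologs above ~50% identity share many). Output feeds
#' [best_hit_assign()].
#'
#' @param genome An `annotated_genome`.
#' @param refdb Reference catalogue tibble.
#' @param min_kmer_share Minimum shared distinct k-mer fraction
#'   (intersection over the smaller set) for a pair to be aligned. Set to 0
#'   to align everything.
#' @param k K-mer length for the prefilter (default 4).
#' @return A hit tibble (see [align_identity()]).
#' @export
compute_hits <- function(genome, refdb, min_kmer_share = 0.05, k = 4L) {
  stopifnot(inherits(genome, "annotated_genome"))
  qk <- kmer_sets(genome$genes$sequence, k)
  rk <- kmer_sets(refdb$sequence, k)
  hits <- purrr::list_rbind(purrr::map(seq_len(nrow(refdb)), function(i) {
    share <- purrr::map_dbl(qk, function(s) {
      length(intersect(s, rk[[i]])) / min(length(s), length(rk[[i]]))
    })
    cand <- which(share >= min_kmer_share)
    if (length(cand) == 0L) {
      return(NULL)
    }
    align_identity(
      query = genome$genes$sequence[cand],
      target = refdb$sequence[i],
      query_id = genome$genes$gene_id[cand],
      ref_id = refdb$ref_id[i]
    )
  }))
  if (is.null(hits)) {
    return(align_identity("A", "A")[0, ])
  }
  hits
}

# Distinct k-mer sets of a character vector of sequences.
kmer_sets <- function(seqs, k = 4L) {
  purrr::map(seqs, function(s) {
    n <- nchar(s)
    if (n < k) {
      return(s)
    }
    unique(substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1))
  })
}

#' Parse a 12(+2)-column BLAST-tab / MMseqs2 hit table
#'
#' Columns: `qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore`, optionally followed by `qlen slen`.
#' Percent identity is rescaled to a 0--1 fraction; coverages are aligned
#' span over sequence length, taken from the optional columns or from
#' `length_map`.
#'
#' @param path TSV path (no header).
#' @param length_map Optional named numeric vector of sequence lengths
#'   (names = sequence ids), used when `qlen`/`slen` columns are absent.
#' @return A hit tibble (see [align_identity()]).
#' @export
parse_hit_table <- function(path, length_map = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  bad <- which(!n_col %in% c(12L, 14L))
  if (length(bad) > 0) {
    abort(sprintf(
      "row %d of %s has %d columns; expected 12 or 14.",
      bad[1], path, n_col[bad[1]]
    ), class = "defensome_format_error")
  }
  rows <- purrr::imap(fields, function(f, i) {
    num <- suppressWarnings(as.numeric(f[3:length(f)]))
    if (anyNA(num)) {
      abort(sprintf("row %d of %s has non-numeric fields.", i, path),
        class = "defensome_format_error"
      )
    }
    qspan <- abs(num[6] - num[5]) + 1
    sspan <- abs(num[8] - num[7]) + 1
    qlen <- if (length(f) == 14L) num[11] else unname(length_map[f[1]])
    slen <- if (length(f) == 14L) num[12] else unname(length_map[f[2]])
    if (is.null(qlen) || is.null(slen) || is.na(qlen) || is.na(slen)) {
      abort(sprintf(
        "row %d of %s: sequence lengths unavailable (no qlen/slen columns and no length_map entry).",
        i, path
      ), class = "defensome_format_error")
    }
    tibble::tibble(
      query_id = f[1], ref_id = f[2],
      identity = num[1] / 100,
      query_coverage = qspan / qlen,
      target_coverage = sspan / slen,
      score = num[10], evalue = num[9]
    )
  })
  purrr::list_rbind(rows)
}

#' Write a hit tibble in 14-column BLAST-tab convention
#'
#' Inverse of [parse_hit_table()] up to the fields the hit tibble carries:
#' alignment spans are reconstructed from coverages and the emitted
#' `qlen`/`slen` columns, so a parse/write round trip preserves identity,
#' coverages, score and e-value.
#'
#' @param hits Hit tibble.
#' @param path Output TSV path.
#' @param length_map Named numeric vector of sequence lengths for all
#'   `query_id` and `ref_id` values.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path, length_map) {
  qlen <- unname(length_map[hits$query_id])
  slen <- unname(length_map[hits$ref_id])
  if (anyNA(qlen) || anyNA(slen)) {
    abort("`length_map` must cover every query_id and ref_id.",
      class = "defensome_argument_error"
    )
  }
  qspan <- round(hits$query_coverage * qlen)
  sspan <- round(hits$target_coverage * slen)
  out <- data.frame(
    qseqid = hits$query_id, sseqid = hits$ref_id,
    pident = hits$identity * 100,
    length = pmax(qspan, sspan), mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = qspan, sstart = 1L, send = sspan,
    evalue = ifelse(is.na(hits$evalue), 10, hits$evalue),
    bitscore = hits$score, qlen = qlen, slen = slen
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Assign query proteins to reference entries by filtered best hit
#'
#' Hits with `identity < min_identity` or
#' `min(query_coverage, target_coverage) < min_coverage` are discarded
#' (both-sided coverage, the `cov_mod 0` convention). Among a query's
#' surviving hits the lowest e-value wins; when e-values are absent the
#' highest score wins. Ties break by higher score, then lexicographically
#' smallest `ref_id`, making the assignment order-invariant.
#'
#' @param hits Hit tibble.
#' @param refdb Reference catalogue resolving every surviving `ref_id`.
#' @param min_identity,min_coverage Thresholds (defaults 0.65 and 0.8).
#' @return Assignment tibble: `query_id`, `ref_id`, `rm_type`, `role`,
#'   `identity`, `coverage` — at most one row per query.
#' @export
best_hit_assign <- function(hits, refdb, min_identity = 0.65,
                            min_coverage = 0.8) {
  assert_scalar_number(min_identity, "min_identity", min = 0, max = 1)
  assert_scalar_number(min_coverage, "min_coverage", min = 0, max = 1)
  hits <- tibble::as_tibble(hits)
  keep <- hits$identity >= min_identity &
    pmin(hits$query_coverage, hits$target_coverage) >= min_coverage
  surv <- hits[keep, ]
  if (nrow(surv) > 0) {
    unknown <- setdiff(surv$ref_id, refdb$ref_id)
    if (length(unknown) > 0) {
      abort(sprintf(
        "hit table references unknown reference ids: %s",
        paste(head(unknown, 3), collapse = ", ")
      ), class = "defensome_reference_error")
    }
  }
  surv |>
    dplyr::mutate(.evalue = ifelse(is.na(.data$evalue), Inf, .data$evalue)) |>
    dplyr::arrange(
      .data$query_id, .data$.evalue, dplyr::desc(.data$score), .data$ref_id
    ) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE) |>
    dplyr::left_join(
      refdb |> dplyr::select("ref_id", "rm_type", "role"),
      by = "ref_id"
    ) |>
    dplyr::mutate(coverage = pmin(.data$query_coverage, .data$target_coverage)) |>
    dplyr::select(
      "query_id", "ref_id", "rm_type", "role", "identity", "coverage"
    )
}

#' Write an assignment table as TSV
#'
#' @param assignments Assignment tibble from [best_hit_assign()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  readr::write_tsv(assignments, path)
  invisible(path)
}
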