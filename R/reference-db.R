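#' Valid restriction-modification component roles by type
#'
#' RM systems are built from restriction endonucleases (R), DNA
#' methyltransferases (M) and, for Type I, a specificity subunit (S).
#' Types IIG and IV are single-protein modules combining both activities.
#'
#' @return A tibble with columns `rm_type` and `role`, one row per valid
#'   combination.
#' @export
#' @examples
#' rm_role_table()
rm_role_table <- function() {
  tibble::tribble(
    ~rm_type, ~role,
    "I", "R",
    "I", "M",
    "I", "S",
    "II", "R",
    "II", "M",
    "III", "R",
    "III", "M",
    "IV", "module",
    "IIG", "module"
  )
}

# Component roles required for a full system of each type.
rm_required_roles <- function(rm_type) {
  switch(rm_type,
    I = c("R", "M", "S"),
    II = c("R", "M"),
    III = c("R", "M"),
    IV = "module",
    IIG = "module",
    abort(sprintf("unknown rm_type '%s'", rm_type),
      class = "defensome_argument_error"
    )
  )
}

#' Generate a synthetic RM reference catalogue
#'
#' Emulates a curated restriction-enzyme repository: `n_per_role` random
#' protein sequences for every valid (type, role) combination (see
#' [rm_role_table()]). Sequence lengths are drawn uniformly within 10% of
#' `mean_len`.
#'
#' @param n_per_role Number of reference entries per (type, role) combination.
#' @param mean_len Mean protein length in residues (minimum 30).
#' @param seed Integer seed; the catalogue is a pure function of the
#'   arguments.
#' @return A tibble with columns `ref_id`, `rm_type`, `role`, `sequence`.
#' @export
#' @examples
#' refdb <- generate_reference_db(n_per_role = 2, mean_len = 100, seed = 1)
#' dplyr::count(refdb, rm_type, role)
generate_reference_db <- function(n_per_role, mean_len = 120L, seed = 1L) {
  assert_scalar_number(n_per_role, "n_per_role", min = 1)
  assert_scalar_number(mean_len, "mean_len", min = 30)
  combos <- rm_role_table()
  with_seed(seed, {
    entries <- purrr::pmap(combos, function(rm_type, role) {
      lens <- pmax(30L, round(runif(n_per_role, mean_len * 0.9, mean_len * 1.1)))
      tibble::tibble(
        ref_id = sprintf("%s-%s-%02d", rm_type, role, seq_len(n_per_role)),
        rm_type = rm_type,
        role = role,
        sequence = purrr::map_chr(lens, random_aa)
      )
    })
    purrr::list_rbind(entries)
  })
}

#' Mutate a protein sequence to a target identity
#'
#' Substitutes exactly `round((1 - target_identity) * nchar(sequence))`
#' positions (chosen at random) with different residues, so the fraction of
#' positions equal to the input is within 1/length of `target_identity`.
#' Used to plant homologs above or below a search identity threshold.
#'
#' @param sequence Amino-acid string.
#' @param target_identity Fraction in (0, 1].
#' @param seed Integer seed.
#' @return A string of the same length as `sequence`.
#' @export
#' @examples
#' s <- strrep("MKVLAGRSTW", 10)
#' mutated <- mutate_to_identity(s, 0.7, seed = 3)
#' mean(strsplit(s, "")[[1]] == strsplit(mutated, "")[[1]])
mutate_to_identity <- function(sequence, target_identity, seed = 1L) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    abort("`sequence` must be a single non-empty string.",
      class = "defensome_argument_error"
    )
  }
  assert_scalar_number(target_identity, "target_identity",
    min = 0, max = 1, allow_min = FALSE
  )
  len <- nchar(sequence)
  n_mut <- round((1 - target_identity) * len)
  if (n_mut == 0L) {
    return(sequence)
  }
  with_seed(seed, {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    idx <- sample.int(len, n_mut)
    chars[idx] <- purrr::map_chr(chars[idx], function(ch) {
      sample(setdiff(AA_ALPHABET20, ch), 1L)
    })
    paste(chars, collapse = "")
  })
}

#' Write / read a reference catalogue as FASTA
#'
#' Headers follow the `ref_id|rm_type|role` convention so role metadata
#' survives a round trip through plain FASTA.
#'
#' @param refdb Tibble as returned by [generate_reference_db()].
#' @param path File path.
#' @return `write_reference_fasta()` returns `path` invisibly;
#'   `read_reference_fasta()` returns the catalogue tibble.
#' @export
write_reference_fasta <- function(refdb, path) {
  seqs <- Biostrings::AAStringSet(refdb$sequence)
  names(seqs) <- paste(refdb$ref_id, refdb$rm_type, refdb$role, sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  parts <- stringr::str_split_fixed(names(seqs), stringr::fixed("|"), 3)
  tibble::tibble(
    ref_id = parts[, 1],
    rm_type = parts[, 2],
    role = parts[, 3],
    sequence = unname(as.character(seqs))
  )
}
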