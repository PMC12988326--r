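#' Plan a synthetic genome
#'
#' A plan entry fixes everything the generator will plant in one genome:
#' which defense systems (RM systems by type, plus non-RM systems detected
#' by external tools), how many decoy genes, and at what sequence identity
#' planted RM components sit relative to the reference catalogue. The plan
#' is the ground truth that downstream recovery tests compare against.
#'
#' @param genome_id Genome identifier.
#' @param systems Tibble with columns `system_name`, `rm_type` (one of
#'   `"I","II","III","IV","IIG"`, or `NA` for non-RM systems), and optionally
#'   `n_genes` (gene count for non-RM systems, default 2) and `roles`
#'   (list-column overriding the planted component roles, e.g. to plant a
#'   lone `II-R` gene). Default roles are the full complement for the type.
#' @param n_decoys Number of random decoy genes interleaved between systems.
#' @param identity Planted sequence identity of RM components to their
#'   reference entries, in (0, 1].
#' @param intersperse Total number of decoy genes (0--2) interleaved inside
#'   each planted operon, spread across the gaps between components.
#' @param n_dms,n_vspr Number of decoy "DMS" / "VSPR" rows the emulated
#'   external tool will report for this genome.
#' @param tool_rm_fraction Fraction of planted RM systems the (weaker)
#'   emulated external tool also reports, exercising the merge policy.
#' @param contig Contig name genes are placed on.
#' @return A list of class `genome_plan`.
#' @export
plan_genome <- function(genome_id, systems = NULL, n_decoys = 15L,
                        identity = 0.75, intersperse = 0L,
                        n_dms = 0L, n_vspr = 0L, tool_rm_fraction = 0,
                        contig = "c1") {
  assert_scalar_number(identity, "identity", min = 0, max = 1, allow_min = FALSE)
  assert_scalar_number(n_decoys, "n_decoys", min = 0)
  assert_scalar_number(intersperse, "intersperse", min = 0, max = 2)
  if (is.null(systems)) {
    systems <- tibble::tibble(
      system_name = character(), rm_type = character()
    )
  }
  systems <- tibble::as_tibble(systems)
  if (!"n_genes" %in% names(systems)) systems$n_genes <- 2L
  if (!"roles" %in% names(systems)) systems$roles <- list(NULL)
  bad <- !is.na(systems$rm_type) &
    !systems$rm_type %in% c("I", "II", "III", "IV", "IIG")
  if (any(bad)) {
    abort("`systems$rm_type` must be one of I, II, III, IV, IIG or NA.",
      class = "defensome_argument_error"
    )
  }
  structure(
    list(
      genome_id = genome_id, systems = systems, n_decoys = as.integer(n_decoys),
      identity = identity, intersperse = as.integer(intersperse),
      n_dms = as.integer(n_dms), n_vspr = as.integer(n_vspr),
      tool_rm_fraction = tool_rm_fraction, contig = contig
    ),
    class = "genome_plan"
  )
}

# Effective planted roles for one planned system row.
planned_roles <- function(rm_type, roles) {
  if (!is.null(roles)) roles else rm_required_roles(rm_type)
}

#' Generate an annotated genome from a plan
#'
#' Lays genes out on a single linear contig in coordinate order with 1-based
#' inclusive, non-overlapping coordinates. Planted operon components are
#' placed consecutively (optionally interspersed with up to 2 decoy genes,
#' still within the 11-gene window the neighborhood rule scans), RM
#' components are mutated copies of matching reference entries at the
#' planned identity, and remaining slots are filled with random decoy
#' proteins.
#'
#' @param plan A `genome_plan` from [plan_genome()].
#' @param refdb Reference catalogue tibble (see [generate_reference_db()]).
#' @param seed Integer seed; output is a pure function of (plan, refdb, seed).
#' @return A list of class `annotated_genome` with elements
#'   `genes` (tibble: genome_id, contig, gene_index, gene_id, start, end,
#'   strand, sequence) and `truth` (tibble: one row per planted system with
#'   its gene ids and roles).
#' @export
generate_genome <- function(plan, refdb, seed = 1L) {
  stopifnot(inherits(plan, "genome_plan"))
  systems <- plan$systems
  n_sys <- nrow(systems)
  with_seed(seed, {
    blocks <- list() # each block: tibble(kind, system_idx, rm_type, role, sequence)
    decoy_block <- function(n) {
      if (n == 0L) {
        return(NULL)
      }
      tibble::tibble(
        kind = "decoy", system_idx = NA_integer_,
        rm_type = NA_character_, role = NA_character_,
        sequence = purrr::map_chr(
          pmax(30L, round(runif(n, 80, 140))), random_aa
        )
      )
    }
    sys_block <- function(i) {
      row <- systems[i, ]
      if (is.na(row$rm_type)) {
        genes <- tibble::tibble(
          kind = "system", system_idx = i,
          rm_type = NA_character_, role = NA_character_,
          sequence = purrr::map_chr(rep(100L, row$n_genes %||% 2L), random_aa)
        )
      } else {
        roles <- planned_roles(row$rm_type, row$roles[[1]])
        if (length(roles) + plan$intersperse > 11L) {
          abort("planted operon exceeds the 11-gene neighborhood window.",
            class = "defensome_argument_error"
          )
        }
        genes <- purrr::map(roles, function(role) {
          pool <- refdb[refdb$rm_type == row$rm_type & refdb$role == role, ]
          if (nrow(pool) == 0L) {
            abort(sprintf(
              "reference catalogue has no entry for type %s role %s",
              row$rm_type, role
            ), class = "defensome_argument_error")
          }
          ref <- pool[sample.int(nrow(pool), 1L), ]
          tibble::tibble(
            kind = "system", system_idx = i, rm_type = row$rm_type,
            role = role,
            sequence = mutate_to_identity(
              ref$sequence, plan$identity,
              seed = sample.int(2^31 - 1, 1L)
            )
          )
        })
        if (plan$intersperse > 0L && length(genes) > 1L) {
          # spread the interspersed decoys round-robin over the gaps so every
          # component stays within the detection window of the anchor
          n_gaps <- length(genes) - 1L
          per_gap <- diff(round(seq(0, plan$intersperse, length.out = n_gaps + 1L)))
          spaced <- list(genes[[1]])
          for (gi in seq_len(n_gaps)) {
            spaced <- c(spaced, list(decoy_block(per_gap[gi])), list(genes[[gi + 1L]]))
          }
          genes <- spaced
        }
        genes <- purrr::list_rbind(purrr::compact(genes))
      }
      genes
    }

    # Interleave systems with decoy runs: decoys split into n_sys + 1 runs.
    run_sizes <- if (n_sys == 0L) {
      plan$n_decoys
    } else {
      as.vector(stats::rmultinom(1, plan$n_decoys, rep(1, n_sys + 1L)))
    }
    blocks <- list(decoy_block(run_sizes[1]))
    for (i in seq_len(n_sys)) {
      blocks <- c(blocks, list(sys_block(i)), list(decoy_block(run_sizes[i + 1L])))
    }
    genes <- purrr::list_rbind(purrr::compact(blocks))

    n <- nrow(genes)
    lens_nt <- nchar(genes$sequence) * 3L + 3L
    gaps <- round(runif(n, 20, 120))
    starts <- cumsum(c(1L, head(lens_nt + gaps, -1L)))
    genes <- genes |>
      dplyr::mutate(
        genome_id = plan$genome_id,
        contig = plan$contig,
        gene_index = dplyr::row_number(),
        gene_id = paste(plan$genome_id, plan$contig, .data$gene_index, sep = "|"),
        start = starts,
        end = starts + lens_nt - 1L,
        strand = sample(c("+", "-"), n, replace = TRUE)
      )

    truth <- genes |>
      dplyr::filter(!is.na(.data$system_idx)) |>
      dplyr::group_by(.data$system_idx) |>
      dplyr::summarise(
        gene_ids = list(.data$gene_id),
        gene_indices = list(.data$gene_index),
        roles = list(.data$role),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        genome_id = plan$genome_id,
        contig = plan$contig,
        system_name = systems$system_name[.data$system_idx],
        rm_type = systems$rm_type[.data$system_idx],
        # A planted RM operon is complete iff all required roles are present.
        complete = purrr::map2_lgl(.data$rm_type, .data$roles, function(ty, ro) {
          if (is.na(ty)) TRUE else all(rm_required_roles(ty) %in% ro)
        })
      ) |>
      dplyr::select(
        "genome_id", "contig", "system_name", "rm_type",
        "gene_ids", "gene_indices", "roles", "complete"
      )

    structure(
      list(
        genes = genes |>
          dplyr::select(
            "genome_id", "contig", "gene_index", "gene_id",
            "start", "end", "strand", "sequence"
          ),
        truth = truth
      ),
      class = "annotated_genome"
    )
  })
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf(
    "<annotated_genome> %s: %d genes, %d planted systems\n",
    x$genes$genome_id[1] %||% "?", nrow(x$genes), nrow(x$truth)
  ))
  invisible(x)
}

#' Simulate assembly incompleteness by random gene dropout
#'
#' Each gene is retained independently with probability `completeness`;
#' coordinates of surviving genes are unchanged. This models the per-gene
#' loss that incomplete metagenome-assembled genomes impose on
#' neighborhood-based detection.
#'
#' @param genome An `annotated_genome`.
#' @param completeness Retention probability in (0, 1].
#' @param seed Integer seed.
#' @return An `annotated_genome` with a subset of the genes; the truth
#'   table is carried over unchanged (planted systems may now be partial).
#' @export
apply_incompleteness <- function(genome, completeness, seed = 1L) {
  stopifnot(inherits(genome, "annotated_genome"))
  assert_scalar_number(completeness, "completeness",
    min = 0, max = 1, allow_min = FALSE
  )
  if (completeness == 1) {
    return(genome)
  }
  with_seed(seed, {
    keep <- runif(nrow(genome$genes)) <= completeness
    genome$genes <- genome$genes[keep, ]
    genome
  })
}

#' Write an annotated genome to protein FASTA and GFF3
#'
#' FASTA records are named by `gene_id` (`genome_id|contig|gene_index`);
#' the GFF3 carries one CDS feature per gene with a matching `ID` attribute
#' and 1-based inclusive coordinates.
#'
#' @param genome An `annotated_genome`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector with the `fasta` and `gff`
#'   paths.
#' @export
write_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gid <- genome$genes$genome_id[1]
  fasta <- file.path(dir, paste0(gid, ".faa"))
  gff <- file.path(dir, paste0(gid, ".gff3"))
  seqs <- Biostrings::AAStringSet(genome$genes$sequence)
  names(seqs) <- genome$genes$gene_id
  Biostrings::writeXStringSet(seqs, fasta)
  gr <- GenomicRanges::GRanges(
    seqnames = genome$genes$contig,
    ranges = IRanges::IRanges(genome$genes$start, genome$genes$end),
    strand = genome$genes$strand,
    type = "CDS",
    phase = 0L,
    ID = genome$genes$gene_id
  )
  rtracklayer::export.gff3(gr, gff)
  invisible(c(fasta = fasta, gff = gff))
}

#' Read an annotated genome from protein FASTA and GFF3
#'
#' @param fasta,gff Paths written by [write_genome()].
#' @param genome_id Genome identifier; defaults to the FASTA basename.
#' @return An `annotated_genome` (with an empty truth table).
#' @export
read_genome <- function(fasta, gff, genome_id = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta)
  gr <- rtracklayer::import(gff)
  gid <- genome_id %||% sub("\\.faa$", "", basename(fasta))
  feat <- tibble::tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gr$ID
  )
  genes <- feat |>
    dplyr::mutate(sequence = unname(as.character(seqs)[.data$gene_id])) |>
    dplyr::arrange(.data$contig, .data$start) |>
    dplyr::group_by(.data$contig) |>
    dplyr::mutate(gene_index = dplyr::row_number(), genome_id = gid) |>
    dplyr::ungroup() |>
    dplyr::select(
      "genome_id", "contig", "gene_index", "gene_id",
      "start", "end", "strand", "sequence"
    )
  structure(
    list(genes = genes, truth = tibble::tibble()),
    class = "annotated_genome"
  )
}

#' Simulate a cohort of genomes with planted RM systems
#'
#' Convenience wrapper used throughout validation: every genome gets one
#' planted operon of each requested RM type (plus any extra non-RM systems),
#' then gene dropout at the requested completeness. Per-genome RNG streams
#' are derived from the master seed, so the cohort is reproducible.
#'
#' @param n_genomes Number of genomes.
#' @param refdb Reference catalogue.
#' @param rm_types RM types planted in every genome.
#' @param identity Planted component identity.
#' @param completeness Gene retention probability in (0, 1].
#' @param n_decoys Decoy genes per genome.
#' @param extra_systems Optional tibble of additional non-RM systems (see
#'   [plan_genome()]).
#' @param n_dms,n_vspr,tool_rm_fraction Passed to [plan_genome()].
#' @param drop_roles Optional character vector of `"type:role"` strings
#'   (e.g. `"I:S"`) removed from every planted operon, for ablation tests.
#' @param seed Master seed.
#' @return A list with `genomes` (list of `annotated_genome`) and `truth`
#'   (combined ground-truth tibble across genomes).
#' @export
simulate_rm_cohort <- function(n_genomes, refdb,
                               rm_types = c("I", "II", "III", "IV", "IIG"),
                               identity = 0.75, completeness = 1,
                               n_decoys = 12L, extra_systems = NULL,
                               n_dms = 0L, n_vspr = 0L, tool_rm_fraction = 0,
                               drop_roles = character(), seed = 1L) {
  assert_scalar_number(n_genomes, "n_genomes", min = 1)
  systems <- tibble::tibble(
    system_name = paste0("RM_type_", rm_types),
    rm_type = rm_types,
    n_genes = NA_integer_,
    roles = purrr::map(rm_types, function(ty) {
      roles <- rm_required_roles(ty)
      dropped <- sub(paste0("^", ty, ":"), "", grep(paste0("^", ty, ":"), drop_roles, value = TRUE))
      keep <- setdiff(roles, dropped)
      if (length(keep) == 0L) {
        abort("cannot drop every role of a planted operon.",
          class = "defensome_argument_error"
        )
      }
      keep
    })
  )
  if (!is.null(extra_systems)) {
    extra_systems <- tibble::as_tibble(extra_systems)
    if (!"n_genes" %in% names(extra_systems)) extra_systems$n_genes <- 2L
    extra_systems$roles <- list(NULL)
    systems <- dplyr::bind_rows(systems, extra_systems)
  }
  genomes <- purrr::map(seq_len(n_genomes), function(i) {
    gseed <- derive_seed(seed, i)
    plan <- plan_genome(
      genome_id = sprintf("g%04d", i), systems = systems,
      n_decoys = n_decoys, identity = identity,
      n_dms = n_dms, n_vspr = n_vspr, tool_rm_fraction = tool_rm_fraction
    )
    g <- generate_genome(plan, refdb, seed = gseed)
    apply_incompleteness(g, completeness, seed = derive_seed(gseed, 1))
  })
  truth <- purrr::list_rbind(purrr::map(genomes, "truth"))
  list(genomes = genomes, truth = truth)
}
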