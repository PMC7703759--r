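# Fragment-based ANI/AF estimation (FastANI-style, re-implemented at desk
# scale) and the species-assignment rule.
#
# The query is cut into consecutive non-overlapping fragments (default 3 kb);
# each fragment is mapped to the reference by exact k-mer seeding on both
# strands, the diagonal with the most seeds is extended ungapped over the
# whole fragment, and the fragment's identity is matches/fragment_length.
# Fragments with identity >= 0.8 count as aligned; ANI is the mean identity
# over aligned fragments and AF the aligned fraction of query fragments.

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(seq) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  substring(seq, 1:(n - k + 1L), k:n)
}

#' Fragment-based ANI between two genomes
#'
#' @param query Named character vector of query contig sequences (names
#'   optional), or a single sequence string.
#' @param reference Named character vector of reference contig sequences.
#' @param k K-mer size for seeding (default 16).
#' @param fragment_len Fragment length in bases (default 3000; must be at
#'   least `10 * k`).
#' @param min_identity Per-fragment identity floor for a fragment to count
#'   as aligned (default 0.8).
#' @param reference_id Id recorded on the result.
#' @return List of class `ani_result` with `reference`, `ani_pct` (`NA` when
#'   no fragment aligns), `align_frac`, `n_fragments`, `warnings`.
#' @export
fragment_ani <- function(query, reference, k = 16L, fragment_len = 3000L,
                         min_identity = 0.8, reference_id = NA_character_) {
  if (fragment_len < 10L * k) {
    tp_error("fragment_len must be at least 10 * k",
             "taxoplace_validation_error")
  }
  query <- as.character(query)
  reference <- as.character(reference)
  if (length(query) == 0L || !any(nzchar(query)) ||
      length(reference) == 0L || !any(nzchar(reference))) {
    tp_error("empty genome", "taxoplace_validation_error")
  }
  warnings <- character()

  # fragments never span contigs; trailing partials are dropped, except that
  # a genome shorter than one fragment yields a single truncated fragment
  frags <- character()
  for (ctg in query) {
    nfull <- nchar(ctg) %/% fragment_len
    if (nfull > 0L) {
      starts <- (seq_len(nfull) - 1L) * fragment_len + 1L
      frags <- c(frags, substring(ctg, starts, starts + fragment_len - 1L))
    }
  }
  if (length(frags) == 0L) {
    frags <- query[which.max(nchar(query))]
    warnings <- c(warnings, "query shorter than one fragment; using a single truncated fragment")
  }

  # reference index: one concatenated string with N-blocks between contigs so
  # no k-mer spans a boundary
  ref_cat <- paste(toupper(reference), collapse = strrep("N", k))
  ref_kmers <- seq_kmers(ref_cat, k)
  ref_raw <- charToRaw(ref_cat)
  ref_len <- length(ref_raw)

  n_frag <- length(frags)
  frags <- toupper(frags)
  rcfrags <- vapply(frags, revcomp, character(1), USE.NAMES = FALSE)

  # one match() over the k-mers of every fragment and strand, so the
  # reference k-mer table is hashed once
  all_frags <- c(frags, rcfrags)
  km_list <- lapply(all_frags, seq_kmers, k = k)
  pos_all <- match(unlist(km_list), ref_kmers)
  idx <- rep.int(seq_along(km_list), lengths(km_list))
  pos_split <- split(pos_all, factor(idx, levels = seq_along(km_list)))

  ident <- numeric(n_frag)
  for (i in seq_len(n_frag)) {
    ident[i] <- max(
      diagonal_identity(frags[i], pos_split[[i]], ref_raw, ref_len),
      diagonal_identity(rcfrags[i], pos_split[[n_frag + i]], ref_raw, ref_len)
    )
  }
  aligned <- ident >= min_identity
  ani <- if (any(aligned)) 100 * mean(ident[aligned]) else NA_real_
  structure(list(reference = reference_id,
                 ani_pct = ani,
                 align_frac = sum(aligned) / n_frag,
                 n_fragments = n_frag,
                 warnings = warnings),
            class = "ani_result")
}

# identity of one fragment strand at its best seed diagonal: ungapped
# comparison of the whole fragment at the modal seed offset
diagonal_identity <- function(f, pos, ref_raw, ref_len) {
  hit <- which(!is.na(pos))
  if (length(hit) == 0L) return(0)
  diags <- pos[hit] - hit            # ref offset of fragment start
  tab <- tabulate(match(diags, unique(diags)))
  diag <- unique(diags)[which.max(tab)]
  fl <- nchar(f)
  lo <- max(1L, diag + 1L)
  hi <- min(ref_len, diag + fl)
  if (hi < lo) return(0)
  fr <- charToRaw(f)
  sum(fr[(lo - diag):(hi - diag)] == ref_raw[lo:hi]) / fl
}

#' Assign a query to a species by ANI
#'
#' Implements the species rule: among ANI results whose alignment fraction
#' strictly exceeds `af_threshold`, take the reference with the highest ANI
#' (ties: lexicographically smallest species name, with a warning) and
#' assign its species iff the ANI is at or above that species'
#' circumscription radius.
#'
#' @param ani_results List of `ani_result` objects (see [fragment_ani()]).
#' @param radii data.frame with `species_name`, `representative_genome`,
#'   `radius_pct` (see [read_radii()]); a species absent from the table gets
#'   `default_radius`.
#' @param af_threshold Alignment-fraction threshold, strict (default 0.65).
#' @param default_radius Default circumscription radius in percent
#'   (default 95).
#' @return List with `species` (name or `NA`), `reference`, `ani_pct`,
#'   `align_frac`, `radius_pct`, `warnings`. `species` is `NA` when no
#'   assignment is possible (novel species or no candidates).
#' @export
species_assign <- function(ani_results, radii, af_threshold = 0.65,
                           default_radius = 95) {
  none <- list(species = NA_character_, reference = NA_character_,
               ani_pct = NA_real_, align_frac = NA_real_,
               radius_pct = NA_real_, warnings = character())
  if (length(ani_results) == 0L) return(none)
  keep <- Filter(function(r) !is.na(r$ani_pct) && r$align_frac > af_threshold,
                 ani_results)
  if (length(keep) == 0L) return(none)
  species_of <- function(ref) {
    i <- match(ref, radii$representative_genome)
    if (is.na(i)) NA_character_ else radii$species_name[i]
  }
  anis <- vapply(keep, function(r) r$ani_pct, numeric(1))
  top <- which(anis == max(anis))
  warnings <- character()
  if (length(top) > 1L) {
    sp <- vapply(keep[top], function(r) species_of(r$reference), character(1))
    o <- order(sp, na.last = TRUE)
    top <- top[o[1]]
    warnings <- c(warnings, "ANI tie; kept lexicographically smallest species")
  }
  best <- keep[[top]]
  sp <- species_of(best$reference)
  radius <- default_radius
  if (!is.na(sp)) {
    i <- match(best$reference, radii$representative_genome)
    if (!is.na(radii$radius_pct[i])) radius <- radii$radius_pct[i]
  } else {
    warnings <- c(warnings, sprintf(
      "reference %s absent from radii table; using default radius %.1f",
      best$reference, default_radius))
  }
  if (best$ani_pct >= radius && !is.na(sp)) {
    list(species = sp, reference = best$reference, ani_pct = best$ani_pct,
         align_frac = best$align_frac, radius_pct = radius,
         warnings = warnings)
  } else {
    none$warnings <- warnings
    none$reference <- best$reference
    none$ani_pct <- best$ani_pct
    none$align_frac <- best$align_frac
    none$radius_pct <- radius
    none
  }
}
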