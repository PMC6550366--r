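#' Construct an annotated fosmid record
#'
#' @param fosmid_id,library_id Labels.
#' @param insert_sequence DNA string.
#' @param orfs data.frame with columns `start`, `end` (1-based inclusive),
#'   `strand` (`"+"`/`"-"`), `family` (GHnn / CEnn / CBMnn / SusC / SusD /
#'   unannotated). Re-sorted by start.
#' @return A `fosmid_record` object.
#' @export
fosmid_record <- function(fosmid_id, library_id = NA_character_,
                          insert_sequence, orfs) {
  stopifnot(is.character(insert_sequence), nchar(insert_sequence) > 0,
            is.data.frame(orfs),
            all(c("start", "end", "strand", "family") %in% names(orfs)))
  len <- nchar(insert_sequence)
  if (nrow(orfs) > 0) {
    if (any(orfs$start < 1) || any(orfs$end > len) || any(orfs$start > orfs$end))
      stop("ORF coordinates must satisfy 1 <= start <= end <= insert length",
           call. = FALSE)
    if (!all(orfs$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'", call. = FALSE)
    ok <- grepl("^(GH|CE|CBM)[0-9]+$", orfs$family) |
      orfs$family %in% c("SusC", "SusD", "unannotated")
    if (!all(ok))
      stop(sprintf("unrecognized family label(s): %s",
                   paste(unique(orfs$family[!ok]), collapse = ", ")), call. = FALSE)
    orfs <- orfs[order(orfs$start), , drop = FALSE]
    rownames(orfs) <- NULL
  }
  fr <- list(fosmid_id = fosmid_id, library_id = library_id,
             insert_sequence = insert_sequence, orfs = orfs)
  class(fr) <- "fosmid_record"
  fr
}

#' Coerce simulated clones to fosmid records
#'
#' @param clones List of `gh_clone` objects whose inserts have been
#'   simulated.
#' @return List of `fosmid_record` objects.
#' @export
as_fosmid_records <- function(clones) {
  lapply(clones, function(cl) {
    if (is.null(cl$insert_sequence))
      stop(sprintf("clone %s has no simulated insert", cl$clone_id), call. = FALSE)
    fosmid_record(cl$clone_id, cl$library_id, cl$insert_sequence, cl$annotation)
  })
}

kmer_set <- function(seq, k = 15) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

kmer_containment <- function(set_a, set_b) {
  if (length(set_a) == 0 || length(set_b) == 0) return(0)
  length(intersect(set_a, set_b)) / min(length(set_a), length(set_b))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Pairwise identity and coverage of two inserts
#'
#' End-gap-free global alignment (Needleman-Wunsch, "overlap" type) of the
#' pair; identity is matches over alignment columns (internal gaps counted,
#' end gaps excluded), coverage is the aligned span over the length of the
#' shorter sequence. With `orientation = "both"` (default) the
#' reverse-complement of `seq_b` is also tried and the orientation with the
#' higher identity wins, so the metric is orientation-invariant; it is also
#' symmetric in its arguments.
#'
#' @param seq_a,seq_b Nonempty DNA strings.
#' @param orientation `"both"`, `"forward"` or `"reverse"`.
#' @return A list with `identity` and `coverage` (fractions in \[0, 1\]).
#' @export
pairwise_identity <- function(seq_a, seq_b, orientation = c("both", "forward", "reverse")) {
  orientation <- match.arg(orientation)
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  align_one <- function(b) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seq_a), Biostrings::DNAString(b),
      type = "overlap", substitutionMatrix = mat,
      gapOpening = 4, gapExtension = 1)
    cols <- nchar(as.character(Biostrings::alignedPattern(al)))
    matches <- Biostrings::nmatch(al)
    shorter_is_a <- nchar(seq_a) <= nchar(b)
    span <- if (shorter_is_a) Biostrings::width(Biostrings::pattern(al))
            else Biostrings::width(Biostrings::subject(al))
    list(identity = matches / cols,
         coverage = span / min(nchar(seq_a), nchar(b)))
  }
  res <- switch(orientation,
    forward = align_one(seq_b),
    reverse = align_one(revcomp(seq_b)),
    both = {
      f <- align_one(seq_b)
      r <- align_one(revcomp(seq_b))
      if (r$identity > f$identity) r else f
    })
  res
}

#' Cluster redundant fosmids
#'
#' Single-linkage clustering on the redundancy relation
#' `identity > id_thresh AND coverage > cov_thresh` (defaults: >95%
#' similarity across >90% of the insert length). Candidate pairs are
#' prefiltered by shared-k-mer containment (k = 15) before alignment, and
#' alignment orientation is chosen by k-mer sharing, so unrelated pairs are
#' never aligned. Fosmids are processed in sorted-ID order, making the
#' partition independent of input order; the representative of each cluster
#' is its longest insert (ties to the lexicographically first ID).
#'
#' @param fosmids List of `fosmid_record` objects.
#' @param id_thresh,cov_thresh Thresholds in (0, 1].
#' @param prefilter Minimum k-mer containment to trigger an alignment.
#' @return A `cluster_set`: list with `clusters` (list of character vectors
#'   of fosmid IDs), `representatives`, `n_clusters`, and the thresholds.
#' @export
cluster_redundant <- function(fosmids, id_thresh = 0.95, cov_thresh = 0.90,
                              prefilter = 0.02) {
  stopifnot(id_thresh > 0, id_thresh <= 1, cov_thresh > 0, cov_thresh <= 1)
  ids <- vapply(fosmids, `[[`, character(1), "fosmid_id")
  if (anyDuplicated(ids)) stop("fosmid IDs must be unique", call. = FALSE)
  ord <- order(ids)
  fosmids <- fosmids[ord]
  ids <- ids[ord]
  n <- length(fosmids)
  seqs <- vapply(fosmids, `[[`, character(1), "insert_sequence")
  lens <- nchar(seqs)
  ksets_f <- lapply(seqs, kmer_set)
  ksets_r <- lapply(seqs, function(s) kmer_set(revcomp(s)))
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        cf <- kmer_containment(ksets_f[[i]], ksets_f[[j]])
        cr <- kmer_containment(ksets_f[[i]], ksets_r[[j]])
        if (max(cf, cr) < prefilter) next
        pid <- pairwise_identity(seqs[i], seqs[j],
                                 orientation = if (cf >= cr) "forward" else "reverse")
        if (pid$identity > id_thresh && pid$coverage > cov_thresh)
          edges <- rbind(edges, c(i, j))
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  clusters <- split(ids, memb)
  names(clusters) <- NULL
  reps <- vapply(clusters, function(members) {
    li <- lens[match(members, ids)]
    members[order(-li, members)][1]
  }, character(1))
  out <- list(clusters = clusters, representatives = reps,
              n_clusters = length(clusters),
              identity_threshold = id_thresh, coverage_threshold = cov_thresh)
  class(out) <- "cluster_set"
  out
}

gh_families <- function(orfs) orfs$family[grepl("^GH[0-9]+$", orfs$family)]

#' Detect polysaccharide utilization loci on a fosmid
#'
#' A PUL call requires the hallmark SusC/SusD-like gene pairing: adjacent
#' ORFs on the same strand with SusC before SusD in transcriptional order
#' (on the minus strand the coordinate order is therefore SusD, SusC).
#' Each call records whether a GH3 occurs within the next three ORFs
#' downstream of the pair (the conserved synteny of these loci) and whether
#' a GH16 or GH144 occurs within a +/- 10-ORF locus window.
#'
#' @param fosmid A `fosmid_record`.
#' @param max_intervening Number of ORFs allowed between SusC and SusD
#'   (default 0, strict adjacency).
#' @return A list of PUL calls, each with `fosmid_id`, `susC_index`,
#'   `susD_index`, `span`, `downstream_gh_families`, `gh3_following`,
#'   `gh16_or_gh144_present`; empty list when no pairing exists.
#' @export
detect_puls <- function(fosmid, max_intervening = 0) {
  orfs <- fosmid$orfs
  n <- nrow(orfs)
  calls <- list()
  if (n < 2) return(calls)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):min(n, i + 1 + max_intervening)) {
      same <- orfs$strand[i] == orfs$strand[j]
      if (!same) next
      plus_pair <- orfs$strand[i] == "+" &&
        orfs$family[i] == "SusC" && orfs$family[j] == "SusD"
      minus_pair <- orfs$strand[i] == "-" &&
        orfs$family[i] == "SusD" && orfs$family[j] == "SusC"
      if (!plus_pair && !minus_pair) next
      ci <- if (plus_pair) i else j       # SusC ORF index
      di <- if (plus_pair) j else i       # SusD ORF index
      downstream <- if (plus_pair) (j + 1):min(n, j + 10) else (i - 1):max(1, i - 10)
      downstream <- downstream[downstream >= 1 & downstream <= n & (
        if (plus_pair) downstream > j else downstream < i)]
      ds_gh <- gh_families(orfs[downstream, , drop = FALSE])
      near3 <- utils::head(downstream, 3)
      window <- max(1, i - 10):min(n, j + 10)
      calls[[length(calls) + 1]] <- list(
        fosmid_id = fosmid$fosmid_id,
        susC_index = ci, susD_index = di,
        span = c(min(orfs$start[i], orfs$start[j]),
                 max(orfs$end[i], orfs$end[j])),
        downstream_gh_families = ds_gh,
        gh3_following = "GH3" %in% orfs$family[near3],
        gh16_or_gh144_present = any(orfs$family[window] %in% c("GH16", "GH144")))
    }
  }
  calls
}

#' Flag fosmids carrying clusters of multiple GH genes
#'
#' @param fosmid A `fosmid_record`.
#' @param min_gh Minimum count of GH-family ORFs (default 5, inclusive).
#' @return List with `flagged` (logical) and `gh_families` (labels present).
#' @export
detect_gh_clusters <- function(fosmid, min_gh = 5) {
  fams <- gh_families(fosmid$orfs)
  list(flagged = length(fams) >= min_gh, gh_families = fams)
}

#' Tabulate GH-family abundance
#'
#' Per-library and overall counts of GH-family ORFs and their percentage of
#' all ORFs (0-100 scale, one decimal).
#'
#' @param fosmids List of `fosmid_record` objects.
#' @return data.frame with columns `library_id` (`"all"` for the overall
#'   rows), `family`, `count`, `percent`.
#' @export
tabulate_gh_abundance <- function(fosmids) {
  if (length(fosmids) == 0)
    return(data.frame(library_id = character(0), family = character(0),
                      count = integer(0), percent = numeric(0)))
  rows <- do.call(rbind, lapply(fosmids, function(f) {
    if (nrow(f$orfs) == 0) return(NULL)
    data.frame(library_id = f$library_id, family = f$orfs$family,
               stringsAsFactors = FALSE)
  }))
  tab_for <- function(df, lib) {
    total <- nrow(df)
    gh <- df$family[grepl("^GH[0-9]+$", df$family)]
    if (length(gh) == 0) return(NULL)
    cnt <- sort(table(gh), decreasing = TRUE)
    data.frame(library_id = lib, family = names(cnt),
               count = as.integer(cnt),
               percent = round(100 * as.integer(cnt) / total, 1),
               stringsAsFactors = FALSE)
  }
  out <- tab_for(rows, "all")
  for (lib in unique(rows$library_id)) {
    out <- rbind(out, tab_for(rows[rows$library_id == lib, , drop = FALSE], lib))
  }
  if (is.null(out))
    out <- data.frame(library_id = character(0), family = character(0),
                      count = integer(0), percent = numeric(0))
  rownames(out) <- NULL
  out
}

#' Clones-per-hit rate
#'
#' `round(clones / hits)` to the nearest integer; `NA` when there are no
#' hits (blank cell in a screening summary).
#'
#' @param clones,hits Non-negative counts, `clones >= hits`.
#' @return Integer clones-per-hit, or `NA_integer_`.
#' @export
hit_rate <- function(clones, hits) {
  if (clones < hits) stop("clones must be >= hits", call. = FALSE)
  if (hits == 0) return(NA_integer_)
  as.integer(round(clones / hits))
}

#' Dual-substrate screen overlap accounting
#'
#' For two screens of the same library (e.g. a chromogenic and a
#' fluorogenic substrate): `unique = hits_a + hits_b - both` clones
#' recovered in either screen, of which `single_substrate = unique - both`
#' were identified with only one substrate.
#'
#' @param hits_a,hits_b Hit counts of the two screens.
#' @param both Clones recovered in both; `both <= min(hits_a, hits_b)`.
#' @return List with `unique` and `single_substrate`.
#' @export
dual_screen_accounting <- function(hits_a, hits_b, both) {
  if (both > min(hits_a, hits_b))
    stop("overlap cannot exceed either screen's hit count", call. = FALSE)
  unique <- hits_a + hits_b - both
  list(unique = unique, single_substrate = unique - both)
}

#' Screening summary statistics
#'
#' Assembles the per-library bookkeeping table (clones screened, hits,
#' clones/hit), totals, optional dual-substrate overlap accounting, and
#' optional ORF statistics over a set of sequenced fosmids (total ORFs,
#' ORFs per fosmid, GH ORFs and their percentage, fosmids with >=
#' `min_gh` GH genes).
#'
#' @param libraries data.frame with columns `library_id`, `clones`, `hits`.
#' @param dual Optional list/vector with `hits_a`, `hits_b`, `both`.
#' @param fosmids Optional list of `fosmid_record` objects.
#' @param min_gh Multi-GH threshold (default 5).
#' @return A `screen_summary` list with elements `per_library` (data.frame
#'   with `clones_per_hit` added), `total_clones`, `total_hits`,
#'   `total_clones_per_hit`, and optionally `dual` and `orf_stats`.
#' @export
screen_summary <- function(libraries, dual = NULL, fosmids = NULL, min_gh = 5) {
  stopifnot(all(c("library_id", "clones", "hits") %in% names(libraries)))
  libraries$clones_per_hit <- mapply(hit_rate, libraries$clones, libraries$hits)
  total_clones <- sum(libraries$clones)
  total_hits <- sum(libraries$hits)
  out <- list(per_library = libraries,
              total_clones = total_clones,
              total_hits = total_hits,
              total_clones_per_hit = hit_rate(total_clones, total_hits))
  if (!is.null(dual)) {
    acc <- dual_screen_accounting(dual[["hits_a"]], dual[["hits_b"]],
                                  dual[["both"]])
    out$dual <- c(list(hits_a = dual[["hits_a"]], hits_b = dual[["hits_b"]],
                       both = dual[["both"]]), acc)
  }
  if (!is.null(fosmids)) {
    n_orfs <- vapply(fosmids, function(f) nrow(f$orfs), integer(1))
    n_gh <- vapply(fosmids, function(f) length(gh_families(f$orfs)), integer(1))
    multi <- sum(n_gh >= min_gh)
    out$orf_stats <- list(
      n_fosmids = length(fosmids),
      total_orfs = sum(n_orfs),
      orfs_per_fosmid = round(sum(n_orfs) / length(fosmids), 1),
      gh_orfs = sum(n_gh),
      gh_percent = round(100 * sum(n_gh) / sum(n_orfs), 1),
      fosmids_with_min_gh = multi,
      fosmids_with_min_gh_percent = round(100 * multi / length(fosmids), 1))
  }
  class(out) <- "screen_summary"
  out
}
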