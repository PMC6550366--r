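#' Write insert sequences as FASTA
#'
#' @param fosmids List of `fosmid_record` (or sequenced `gh_clone`) objects.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_inserts_fasta <- function(fosmids, path) {
  ids <- vapply(fosmids, function(f) f$fosmid_id %||% f$clone_id, character(1))
  seqs <- vapply(fosmids, `[[`, character(1), "insert_sequence")
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read insert sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_inserts_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(dss), names(dss))
}

#' Write ORF annotations as GFF3
#'
#' One `CDS` feature per ORF, 1-based inclusive coordinates, with the
#' family label in the `family` attribute.
#'
#' @param fosmids List of `fosmid_record` objects.
#' @param path Output GFF3 path.
#' @return The path, invisibly.
#' @export
write_annotation_gff3 <- function(fosmids, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (f in fosmids) {
    if (nrow(f$orfs) == 0) next
    lines <- sprintf("%s\tfosmidscreen\tCDS\t%d\t%d\t.\t%s\t0\tID=%s_orf%03d;family=%s",
                     f$fosmid_id, f$orfs$start, f$orfs$end, f$orfs$strand,
                     f$fosmid_id, seq_len(nrow(f$orfs)), f$orfs$family)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read ORF annotations from GFF3
#'
#' Parses the GFF3 written by [write_annotation_gff3()] back into per-fosmid
#' ORF tables.
#'
#' @param path GFF3 path.
#' @return Named list of data.frames (start, end, strand, family), one per
#'   seqid.
#' @export
read_annotation_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(
    seqid = vapply(parts, `[[`, character(1), 1),
    start = as.integer(vapply(parts, `[[`, character(1), 4)),
    end = as.integer(vapply(parts, `[[`, character(1), 5)),
    strand = vapply(parts, `[[`, character(1), 7),
    family = sub(".*family=([^;]+).*", "\\1",
                 vapply(parts, `[[`, character(1), 9)),
    stringsAsFactors = FALSE)
  lapply(split(df[, c("start", "end", "strand", "family")], df$seqid),
         function(x) { rownames(x) <- NULL; x })
}

#' Write plate reads as CSV
#'
#' Long format: `plate_id, library_id, substrate, well, row, col, clone_id,
#' fluorescence`.
#'
#' @param plates List of `plate_read` objects.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_plates_csv <- function(plates, path) {
  if (inherits(plates, "plate_read")) plates <- list(plates)
  df <- do.call(rbind, lapply(plates, function(pl)
    cbind(data.frame(plate_id = pl$plate_id, library_id = pl$library_id,
                     substrate = pl$substrate, stringsAsFactors = FALSE),
          pl$wells)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read plate reads from CSV
#'
#' @param path CSV written by [write_plates_csv()].
#' @return List of `plate_read` objects.
#' @export
read_plates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, factor(df$plate_id, levels = unique(df$plate_id))),
         function(x) plate_read(x$plate_id[1], x$library_id[1], x$substrate[1],
                                x[, c("well", "row", "col", "clone_id",
                                      "fluorescence")]))
}

#' Write time courses as CSV
#'
#' Long format: `clone_id, substrate, condition, conc0, time_s, rfu, od600`.
#'
#' @param tcs List of `timecourse` objects.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_timecourses_csv <- function(tcs, path) {
  if (inherits(tcs, "timecourse")) tcs <- list(tcs)
  df <- do.call(rbind, lapply(tcs, function(tc)
    data.frame(clone_id = tc$clone_id, substrate = tc$substrate,
               condition = if (is.null(tc$condition)) NA else tc$condition,
               conc0 = tc$conc0, time_s = tc$times, rfu = tc$rfu,
               od600 = if (is.null(tc$od600)) NA_real_ else tc$od600,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read time courses from CSV
#'
#' @param path CSV written by [write_timecourses_csv()].
#' @return List of `timecourse` objects.
#' @export
read_timecourses_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- paste(df$clone_id, df$substrate, df$condition, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(x) {
    tc <- list(clone_id = x$clone_id[1], substrate = x$substrate[1],
               conc0 = x$conc0[1], times = x$time_s, rfu = x$rfu,
               od600 = if (all(is.na(x$od600))) NULL else x$od600[1],
               condition = if (all(is.na(x$condition))) NULL else x$condition[1])
    class(tc) <- "timecourse"
    tc
  })
}

#' Write latent ground truth as JSON
#'
#' Serializes clone IDs, addresses and enzyme parameters (not insert
#' sequences) so downstream estimates can be checked against truth.
#'
#' @param clones List of `gh_clone` objects.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_ground_truth_json <- function(clones, path) {
  payload <- lapply(clones, function(cl) {
    list(clone_id = cl$clone_id, library_id = cl$library_id,
         plate = cl$plate, well = cl$well,
         active = is_active(cl),
         enzymes = lapply(cl$enzymes, function(e)
           list(gh_family = e$gh_family, kcat = as.list(e$kcat),
                km = as.list(e$km), ph_optimum = e$ph_optimum,
                ph_width = e$ph_width, tm = e$tm, dh_vh = e$dh_vh,
                mechanism = e$mechanism)))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a screening summary as TSV
#'
#' Tab-separated per-library table (the screening bookkeeping analog) with
#' a `Total` row; blank clones/hit for zero-hit libraries.
#'
#' @param summary A [screen_summary()] object.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_screen_summary_tsv <- function(summary, path) {
  df <- summary$per_library
  total <- data.frame(library_id = "Total", clones = summary$total_clones,
                      hits = summary$total_hits,
                      clones_per_hit = summary$total_clones_per_hit)
  df <- rbind(df[, names(total)], total)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Write a cluster set as TSV
#'
#' @param clusters A `cluster_set` from [cluster_redundant()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_clusters_tsv <- function(clusters, path) {
  df <- do.call(rbind, lapply(seq_along(clusters$clusters), function(i)
    data.frame(cluster = i, fosmid_id = clusters$clusters[[i]],
               representative = clusters$representatives[i],
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write PUL calls as TSV
#'
#' @param calls List of PUL calls from [detect_puls()] (possibly
#'   concatenated over fosmids).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_puls_tsv <- function(calls, path) {
  df <- if (length(calls) == 0) {
    data.frame(fosmid_id = character(0), susC_index = integer(0),
               susD_index = integer(0), span_start = integer(0),
               span_end = integer(0), gh3_following = logical(0),
               gh16_or_gh144_present = logical(0),
               downstream_gh_families = character(0))
  } else {
    do.call(rbind, lapply(calls, function(p)
      data.frame(fosmid_id = p$fosmid_id, susC_index = p$susC_index,
                 susD_index = p$susD_index, span_start = p$span[1],
                 span_end = p$span[2], gh3_following = p$gh3_following,
                 gh16_or_gh144_present = p$gh16_or_gh144_present,
                 downstream_gh_families = paste(p$downstream_gh_families,
                                                collapse = ","),
                 stringsAsFactors = FALSE)))
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
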