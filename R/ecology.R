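#' CRISPR spacer collection
#'
#' @param id spacer ids.
#' @param host_genome genome id each spacer was recovered from.
#' @param sequence DNA strings (A/C/G/T, 20-60 nt); lower case is
#'   normalized to upper case.
#' @return a data.frame of class `spacer_set`.
#' @export
spacer_set <- function(id, host_genome, sequence) {
  sequence <- toupper(sequence)
  if (any(nchar(sequence) == 0)) stop("empty spacer sequence")
  if (any(nchar(sequence) < 20 | nchar(sequence) > 60))
    stop("spacer lengths must be 20-60 nt")
  structure(data.frame(id = id, host_genome = host_genome,
                       sequence = sequence, stringsAsFactors = FALSE),
            class = c("spacer_set", "data.frame"))
}

#' Read spacers from FASTA
#'
#' Header convention `><spacer_id> <host_genome>`; when the description
#' lacks a second token the host genome is taken from the id prefix before
#' the last underscore.
#' @param path FASTA file.
#' @return a `spacer_set`.
#' @export
read_spacer_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  parts <- strsplit(nm, "\\s+")
  id <- vapply(parts, `[[`, character(1), 1)
  host <- vapply(parts, function(p)
    if (length(p) >= 2) p[2] else sub("_[^_]*$", "", p[1]), character(1))
  spacer_set(id, host, as.character(seqs))
}

#' Match CRISPR spacers to viral contigs
#'
#' Ungapped matching of every spacer (both strands) against every vOTU
#' sequence. A hit is retained only when identity, coverage and mismatch
#' count jointly satisfy the thresholds (defaults 97% identity, 90%
#' coverage, at most 1 mismatch). Identity is `matches / aligned length`,
#' coverage `aligned length / spacer length`; partial coverage arises from
#' hits overhanging a contig end. With at most one mismatch permitted,
#' gapped alignment adds nothing, so indels are not modeled. Non-ACGT
#' characters count as mismatches. Interior full-length hits are found with
#' `Biostrings::matchPattern`; end overhangs are scanned directly.
#'
#' @param spacers a `spacer_set`.
#' @param votus named character vector of DNA sequences, or a
#'   `Biostrings::DNAStringSet`, or a FASTA path.
#' @param min_identity,min_coverage percent thresholds.
#' @param max_mismatch maximum mismatches in the aligned region.
#' @return data.frame with one row per retained match: `spacer_id`,
#'   `votu_id`, `host_genome`, `identity`, `coverage`, `mismatches`,
#'   `strand` (+/- relative to the vOTU forward strand), `start`, `end`
#'   (0-based half-open on the vOTU).
#' @export
match_spacers <- function(spacers, votus, min_identity = 97,
                          min_coverage = 90, max_mismatch = 1) {
  if (is.character(votus) && length(votus) == 1 && file.exists(votus))
    votus <- Biostrings::readDNAStringSet(votus)
  if (is.character(votus)) votus <- Biostrings::DNAStringSet(toupper(votus))
  if (is.null(names(votus))) stop("votus must be named")
  if (any(nchar(spacers$sequence) == 0)) stop("empty spacer sequence")

  rows <- list()
  emit <- function(sid, host, vid, strand, start, end, mism, aligned, n) {
    rows[[length(rows) + 1]] <<- data.frame(
      spacer_id = sid, votu_id = vid, host_genome = host,
      identity = (aligned - mism) / aligned * 100,
      coverage = aligned / n * 100, mismatches = as.integer(mism),
      strand = strand, start = as.integer(start), end = as.integer(end),
      stringsAsFactors = FALSE)
  }

  for (v in seq_along(votus)) {
    subject <- votus[[v]]
    vid <- names(votus)[v]
    L <- length(subject)
    subj_chars <- strsplit(as.character(subject), "")[[1]]
    for (s in seq_len(nrow(spacers))) {
      n <- nchar(spacers$sequence[s])
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") spacers$sequence[s] else
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(spacers$sequence[s])))
        # interior full-length hits (coverage 100)
        hits <- Biostrings::matchPattern(pat, subject,
                                         max.mismatch = max_mismatch,
                                         with.indels = FALSE)
        seen <- integer()
        for (h in seq_along(hits)) {
          st <- Biostrings::start(hits)[h]; en <- Biostrings::end(hits)[h]
          if (st < 1 || en > L) next
          mism <- Biostrings::neditStartingAt(Biostrings::DNAString(pat),
                                              subject, starting.at = st,
                                              fixed = TRUE)
          identity <- (n - mism) / n * 100
          if (mism <= max_mismatch && identity >= min_identity &&
              100 >= min_coverage) {
            emit(spacers$id[s], spacers$host_genome[s], vid, strand,
                 st - 1L, en, mism, n, n)
            seen <- c(seen, st - 1L)
          }
        }
        # end overhangs (coverage < 100)
        if (min_coverage < 100) {
          min_aln <- max(1L, as.integer(ceiling(min_coverage / 100 * n -
                                                  1e-9)))
          edge_starts <- unique(c(seq.int(1L - (n - min_aln), 0L),
                                  seq.int(L - n + 1L, L - min_aln + 1L)))
          p <- strsplit(pat, "")[[1]]
          for (start0 in edge_starts) {
            lo <- max(1L, start0); hi <- min(L, start0 + n - 1L)
            aligned <- hi - lo + 1L
            if (aligned < min_aln || aligned == n) next  # full-length done
            mism <- sum(subj_chars[lo:hi] !=
                          p[(lo - start0 + 1):(hi - start0 + 1)])
            identity <- (aligned - mism) / aligned * 100
            coverage <- aligned / n * 100
            if (mism <= max_mismatch && identity >= min_identity &&
                coverage >= min_coverage)
              emit(spacers$id[s], spacers$host_genome[s], vid, strand,
                   lo - 1L, hi, mism, n, n)
          }
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(spacer_id = character(), votu_id = character(),
                      host_genome = character(), identity = numeric(),
                      coverage = numeric(), mismatches = integer(),
                      strand = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("spacer_id", "votu_id", "strand",
                                 "start", "end")]), ]
  rownames(out) <- NULL
  out
}

#' Host infection rate from spacer matches
#'
#' @param matches retained matches from [match_spacers()] (the
#'   `host_genome` column links matches to genomes).
#' @param genomes character vector of all genome ids screened.
#' @return list with `linked_genomes`, `total_genomes`, `rate_percent`
#'   (truncated toward zero, so 92/136 reports 67) and `rate_exact`.
#' @export
infection_rate <- function(matches, genomes) {
  if (!length(genomes)) stop("genomes must be non-empty")
  linked <- length(intersect(unique(matches$host_genome), genomes))
  exact <- linked / length(genomes) * 100
  list(linked_genomes = linked, total_genomes = length(genomes),
       rate_percent = as.integer(floor(exact + 1e-9)), rate_exact = exact)
}

#' Write spacer matches as a BLAST outfmt-6-like TSV
#' @param matches data.frame from [match_spacers()].
#' @param path output file.
#' @export
write_match_tsv <- function(matches, path) {
  df <- data.frame(qseqid = matches$spacer_id, sseqid = matches$votu_id,
                   pident = matches$identity,
                   length = matches$end - matches$start,
                   mismatch = matches$mismatches, qstart = 1,
                   qend = matches$end - matches$start,
                   sstart = matches$start, send = matches$end,
                   strand = matches$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summary of complete defense-system counts across genomes
#'
#' @param ds_counts named integer vector, genome -> number of complete
#'   antiviral defense systems.
#' @return list with `n_genomes`, `total_systems`, `mean_per_genome`
#'   (rounded to one decimal, as customarily reported) and `max_per_genome`.
#' @export
defense_system_summary <- function(ds_counts) {
  if (!length(ds_counts)) stop("ds_counts must be non-empty")
  list(n_genomes = length(ds_counts),
       total_systems = sum(ds_counts),
       mean_per_genome = round(sum(ds_counts) / length(ds_counts), 1),
       max_per_genome = max(ds_counts))
}

#' Spearman correlation of defense-system counts with genome size
#'
#' @param ds_counts named integer vector, genome -> complete defense-system
#'   count.
#' @param genome_sizes named numeric vector, genome -> size in bp (same
#'   names).
#' @return Spearman's rho.
#' @export
ds_size_correlation <- function(ds_counts, genome_sizes) {
  if (!setequal(names(ds_counts), names(genome_sizes)))
    stop("ds_counts and genome_sizes must share the same genomes")
  if (length(ds_counts) < 3) stop("need at least 3 genomes")
  g <- names(ds_counts)
  unname(cor(ds_counts[g], genome_sizes[g], method = "spearman"))
}
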