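#' Amplicon scaffold definition
#'
#' The amplicon reads carry, in forward orientation: a forward demultiplexing
#' region, a forward constant region, the variable insert, a reverse constant
#' region and the reverse complement of the reverse demultiplexing region.
#' Defaults are the scaffold used for the hexadecapeptide display library, so
#' `insert_length_nt = 3 * 16 = 48`.
#'
#' @param fwd_demux,rev_demux Demultiplexing motifs (5'-&gt;3' of their own read).
#' @param fwd_const,rev_const Constant regions flanking the insert, forward
#'   orientation.
#' @param insert_length_nt Required insert length in nucleotides.
#' @return An object of class `amplicon_scaffold`.
#' @export
amplicon_scaffold <- function(fwd_demux = "CTAGCGCT",
                              rev_demux = "CGCAGACG",
                              fwd_const = "ATGCCTATGCAGCCTCTTCATCTGGC",
                              rev_const = paste0(
                                "GGTGGAGGATCCGGAGGAGGCGCCGAGGGTGACGATCCCGCA",
                                "AAAGCGGCCTTTAACTCCCTGCAAGCCTCAGCGACCGAATAT",
                                "ATCGGTTATGCGTGGGCGATGGTTGTTGTCAT"),
                              insert_length_nt = 48L) {
  motifs <- c(fwd_demux, rev_demux, fwd_const, rev_const)
  stopifnot(is.character(motifs), all(nchar(motifs) > 0L),
            all(grepl("^[ACGT]+$", motifs)),
            insert_length_nt >= 3L, insert_length_nt %% 3L == 0L)
  structure(
    list(fwd_demux = fwd_demux, rev_demux = rev_demux,
         fwd_const = fwd_const, rev_const = rev_const,
         insert_length_nt = as.integer(insert_length_nt)),
    class = "amplicon_scaffold"
  )
}

#' Read a FASTQ file into a tibble
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; gzip input is handled
#' transparently. The read id is the first whitespace-delimited token of the
#' header, which is what paired mates share.
#'
#' @param path FASTQ (optionally `.gz`) file path.
#' @return Tibble with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # structural validation first: Biostrings silently tolerates a truncated
  # final record, so check the 4-line record frame ourselves
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    abort(paste0("malformed FASTQ in '", path, "': record ",
                 length(lines) %/% 4L + 1L, " is truncated"))
  }
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  sep <- lines[seq(3L, length(lines), by = 4L)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(sep, "+"))
  if (length(bad)) {
    abort(paste0("malformed FASTQ in '", path, "': record ", bad[1],
                 " violates the @/+ record structure"))
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      abort(paste0("malformed FASTQ in '", path, "': ", conditionMessage(e)))
    }
  )
  q <- S4Vectors::mcols(x)$qualities
  bad <- which(Biostrings::width(q) != Biostrings::width(x))
  if (is.null(q) || length(q) != length(x) || length(bad)) {
    abort(paste0("malformed FASTQ in '", path, "': record ",
                 if (length(bad)) bad[1] else length(x),
                 " has a truncated or missing quality string"))
  }
  qual <- tryCatch(as.character(q), error = function(e) {
    abort(paste0("malformed FASTQ in '", path, "': undecodable qualities"))
  })
  tibble(
    read_id = sub("\\s.*$", "", names(x)),
    seq     = as.character(x),
    qual    = qual
  )
}

#' Join paired-end reads on read id
#'
#' Mates are matched by read id; ids present in only one stream are dropped
#' and tallied in the `n_unpaired_fwd` / `n_unpaired_rev` attributes.
#'
#' @param fwd,rev Tibbles from [read_fastq()] (or paths to FASTQ files).
#' @return Tibble of read pairs: `read_id`, `fwd_seq`, `rev_seq`,
#'   `fwd_qual`, `rev_qual`.
#' @export
join_pairs <- function(fwd, rev) {
  if (is.character(fwd)) fwd <- read_fastq(fwd)
  if (is.character(rev)) rev <- read_fastq(rev)
  stopifnot(all(c("read_id", "seq", "qual") %in% names(fwd)),
            all(c("read_id", "seq", "qual") %in% names(rev)))
  pairs <- inner_join(
    rename(fwd, fwd_seq = "seq", fwd_qual = "qual"),
    rename(rev, rev_seq = "seq", rev_qual = "qual"),
    by = "read_id"
  )
  pairs <- select(pairs, "read_id", "fwd_seq", "rev_seq", "fwd_qual", "rev_qual")
  attr(pairs, "n_unpaired_fwd") <- sum(!fwd$read_id %in% rev$read_id)
  attr(pairs, "n_unpaired_rev") <- sum(!rev$read_id %in% fwd$read_id)
  pairs
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

translate_nt <- function(x) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(x),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

# First-occurrence exact motif positions (-1L where absent); vectorised over x.
motif_pos <- function(x, motif) {
  p <- regexpr(motif, x, fixed = TRUE)
  as.integer(p)
}

#' Extract and filter variable inserts from read pairs
#'
#' For each pair both mates are normalised to forward orientation (the reverse
#' mate is reverse-complemented) and the insert is recovered independently from
#' each as the sequence between the end of the forward constant region and the
#' start of the reverse constant region. A pair is `accepted` only if
#'
#' * the forward demultiplexing motif occurs in the forward mate and the
#'   reverse demultiplexing motif in the reverse mate, and both constant
#'   regions occur in both normalised mates (else `reject_missing_motif`);
#' * the two mate-derived inserts are identical (else `reject_discordant`);
#' * the insert has exactly `insert_length_nt` bases (else `reject_size`);
#' * the insert contains no `N` (else `reject_ambiguous`).
#'
#' Motif search is exact substring match at the first occurrence; no
#' mismatches are tolerated and base qualities are carried but never used.
#'
#' @param pairs Tibble from [join_pairs()].
#' @param scaffold An [amplicon_scaffold()].
#' @return Tibble of insert calls: `read_id`, `status`, `insert_nt`, `peptide`
#'   (`NA` unless accepted; accepted peptides are the translated insert).
#' @export
extract_inserts <- function(pairs, scaffold = amplicon_scaffold()) {
  stopifnot(inherits(scaffold, "amplicon_scaffold"))
  n <- nrow(pairs)
  if (n == 0L) {
    return(tibble(read_id = character(), status = character(),
                  insert_nt = character(), peptide = character()))
  }
  fwd <- toupper(pairs$fwd_seq)
  rev_norm <- revcomp(toupper(pairs$rev_seq))

  insert_between <- function(x, scaffold) {
    lo <- motif_pos(x, scaffold$fwd_const)
    hi <- motif_pos(x, scaffold$rev_const)
    start <- lo + nchar(scaffold$fwd_const)
    ins <- rep(NA_character_, length(x))
    ok <- lo > 0L & hi > 0L & hi >= start
    ins[ok] <- substr(x[ok], start[ok], hi[ok] - 1L)
    list(found = lo > 0L & hi > 0L, insert = ins)
  }

  f <- insert_between(fwd, scaffold)
  r <- insert_between(rev_norm, scaffold)
  demux_ok <- motif_pos(fwd, scaffold$fwd_demux) > 0L &
    motif_pos(toupper(pairs$rev_seq), scaffold$rev_demux) > 0L

  status <- rep("accepted", n)
  status[!(demux_ok & f$found & r$found)] <- "reject_missing_motif"
  live <- status == "accepted"
  disc <- live & (is.na(f$insert) | is.na(r$insert) | f$insert != r$insert)
  status[disc] <- "reject_discordant"
  live <- status == "accepted"
  bad_size <- live & nchar(f$insert) != scaffold$insert_length_nt
  status[bad_size] <- "reject_size"
  live <- status == "accepted"
  ambig <- live & grepl("N", f$insert, fixed = TRUE)
  status[ambig] <- "reject_ambiguous"

  insert_nt <- ifelse(status == "accepted", f$insert, NA_character_)
  peptide <- rep(NA_character_, n)
  acc <- which(status == "accepted")
  if (length(acc)) peptide[acc] <- translate_nt(insert_nt[acc])
  tibble(read_id = pairs$read_id, status = status,
         insert_nt = insert_nt, peptide = peptide)
}

#' Count designed-library variants among accepted insert calls
#'
#' Only peptides that are members of the designed library are counted;
#' accepted peptides outside it are tallied as `off_library`. Rejection
#' tallies from [extract_inserts()] are preserved in the `rejections`
#' attribute, so every read is accounted for exactly once:
#' `n_reads_total = counted + off_library + rejected`.
#'
#' @param calls Tibble from [extract_inserts()].
#' @param designed Character vector: the designed peptide library.
#' @param sample_id Sample label attached to the counts.
#' @return Tibble `sample_id`, `peptide`, `count` (observed peptides only),
#'   with attributes `n_reads_total` and `rejections` (named integer vector).
#' @export
count_variants <- function(calls, designed, sample_id = "sample") {
  stopifnot(length(designed) > 0L)
  if (nrow(calls) == 0L) {
    warn("empty insert-call stream; returning empty count table")
  }
  acc <- filter(calls, .data$status == "accepted")
  on_lib <- filter(acc, .data$peptide %in% designed)
  counts <- count(on_lib, .data$peptide, name = "count")
  counts <- mutate(counts, sample_id = sample_id, .before = 1L)
  rej <- table(factor(calls$status,
                      levels = c("reject_missing_motif", "reject_discordant",
                                 "reject_size", "reject_ambiguous")))
  rejections <- c(stats::setNames(as.integer(rej), names(rej)),
                  off_library = nrow(acc) - nrow(on_lib))
  counts <- arrange(counts, desc(.data$count), .data$peptide)
  attr(counts, "n_reads_total") <- nrow(calls)
  attr(counts, "rejections") <- rejections
  counts
}

#' Tabulate insert-call statuses
#'
#' @param calls Tibble from [extract_inserts()].
#' @return Tibble `status`, `n`.
#' @export
rejection_summary <- function(calls) {
  lv <- c("accepted", "reject_missing_motif", "reject_discordant",
          "reject_size", "reject_ambiguous")
  out <- as.data.frame(table(factor(calls$status, levels = lv)))
  tibble(status = as.character(out$Var1), n = as.integer(out$Freq))
}
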