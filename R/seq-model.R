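# Upstream-sequence I/O and the ATG-relative coordinate frame.
#
# Two coordinate frames are used throughout:
#   * string positions: 1-based inclusive on the stored upstream string,
#     whose last base sits immediately 5' of the ATG;
#   * ATG-relative (upstream) positions: 1-based distances from the ATG,
#     position 1 being the base immediately 5' of the ATG.

#' Read a multi-FASTA of upstream regions
#'
#' Headers use the dialect `geneID|chrom|strand|atgPos`; fields after the
#' gene id are optional.  Sequences are uppercased, `U` is converted to
#' `T`, and any character outside `{A,C,G,T,N}` is rejected.
#'
#' @param path Path to a FASTA file.
#' @param species Species tag recorded for every record.
#' @return An [UpstreamSet-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1|Chr2|+|3541793", strrep("ACGT", 10)), fa)
#' readUpstreamFasta(fa, "cicer")
#' @export
readUpstreamFasta <- function(path, species = "unknown") {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) .stopf("no FASTA records in %s", path)
  headers <- names(x)
  gene_id <- chrom <- character(length(x))
  strand <- character(length(x))
  atg <- integer(length(x))
  for (i in seq_along(x)) {
    fields <- strsplit(sub("\\s.*$", "", headers[i]), "|", fixed = TRUE)[[1]]
    if (length(fields) == 0L || !nzchar(fields[1]))
      .stopf("malformed FASTA header at record %d: '%s'", i, headers[i])
    if (length(fields) > 4L)
      .stopf("malformed FASTA header at record %d (too many '|' fields): '%s'",
             i, headers[i])
    gene_id[i] <- fields[1]
    chrom[i] <- if (length(fields) >= 2L) fields[2] else NA_character_
    strand[i] <- if (length(fields) >= 3L) fields[3] else "*"
    if (length(fields) >= 3L && !fields[3] %in% c("+", "-"))
      .stopf("malformed FASTA header at record %d: bad strand '%s'",
             i, fields[3])
    if (length(fields) >= 4L) {
      pos <- suppressWarnings(as.integer(fields[4]))
      if (is.na(pos))
        .stopf("malformed FASTA header at record %d: bad ATG position '%s'",
               i, fields[4])
      atg[i] <- pos
    } else atg[i] <- NA_integer_
  }
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup))
    .stopf("duplicate gene id(s) in %s: %s", path,
           paste(unique(dup), collapse = ", "))
  seqs <- toupper(chartr("Uu", "Tt", as.character(x)))
  for (i in seq_along(seqs)) {
    bad <- .badBases(seqs[[i]])
    if (length(bad))
      .stopf("record %d (%s): disallowed sequence characters: %s",
             i, gene_id[i], paste(bad, collapse = ", "))
  }
  UpstreamSet(stats::setNames(seqs, gene_id), species = species,
              chromosome = chrom, strand = strand, atgPos = atg)
}

#' Write an UpstreamSet as multi-FASTA
#'
#' Inverse of [readUpstreamFasta()]: headers are rebuilt in the
#' `geneID|chrom|strand|atgPos` dialect (fields that are `NA`/unknown are
#' dropped from the right).
#'
#' @param x An [UpstreamSet-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeUpstreamFasta <- function(x, path) {
  stopifnot(methods::is(x, "UpstreamSet"))
  info <- upstreamInfo(x)
  headers <- character(nrow(info))
  for (i in seq_len(nrow(info))) {
    fields <- c(info$gene_id[i], info$chromosome[i],
                if (info$strand[i] == "*") NA_character_ else info$strand[i],
                as.character(info$atg_pos[i]))
    keep <- max(c(1L, which(!is.na(fields))))
    fields <- fields[seq_len(keep)]
    fields[is.na(fields)] <- ""
    headers[i] <- paste(fields, collapse = "|")
  }
  lines <- character(0)
  seqs <- as.character(upstreamSeqs(x))
  for (i in seq_along(seqs))
    lines <- c(lines, paste0(">", headers[i]), seqs[[i]])
  writeLines(lines, path)
  invisible(path)
}

#' Convert between string positions and the ATG-relative frame
#'
#' Maps a 1-based inclusive interval `(i, j)` on a stored upstream string
#' of length `L` to ATG-relative upstream distances
#' `(start_up, end_up) = (L - j + 1, L - i + 1)`.  The transform is an
#' involution: applying it to its own output returns `(i, j)`.
#'
#' @param start,end Integer vectors, 1-based inclusive interval on the
#'   stored string (or, equivalently, an ATG-relative interval to map
#'   back).
#' @param seqLength Length(s) of the upstream string.
#' @return A data.frame with columns `start_up` and `end_up`.
#' @examples
#' toUpstreamFrame(991, 1000, 1000)   # ten bases nearest the ATG
#' toUpstreamFrame(3, 5, 10)          # (6, 8)
#' @export
toUpstreamFrame <- function(start, end, seqLength) {
  start <- as.integer(start); end <- as.integer(end)
  seqLength <- as.integer(seqLength)
  n <- max(length(start), length(end), length(seqLength))
  start <- rep_len(start, n); end <- rep_len(end, n)
  seqLength <- rep_len(seqLength, n)
  bad <- is.na(start) | is.na(end) | start < 1L | end < start | end > seqLength
  if (any(bad))
    .stopf("interval out of range at index %d: (%s, %s) with L = %s",
           which(bad)[1], start[which(bad)[1]], end[which(bad)[1]],
           seqLength[which(bad)[1]])
  data.frame(start_up = seqLength - end + 1L, end_up = seqLength - start + 1L)
}

#' Write located features as GFF3
#'
#' One line per feature; `seqid` is the gene id of the upstream record and
#' coordinates are 1-based inclusive string positions.  ATG-relative
#' coordinates and any extra columns are carried in the attributes and
#' survive a read-back through [readLociGFF3()].
#'
#' @param loci A data.frame with columns `gene_id`, `start`, `end`, `type`
#'   and optionally `strand`, `ID`, `up_start`, `up_end`.
#' @param path Output path.
#' @param source GFF3 source tag.
#' @return `path`, invisibly.
#' @export
writeLociGFF3 <- function(loci, path, source = "cnmscan") {
  required <- c("gene_id", "start", "end", "type")
  if (!all(required %in% names(loci)))
    .stopf("loci must have columns: %s", paste(required, collapse = ", "))
  if (nrow(loci) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  strand <- if ("strand" %in% names(loci)) loci$strand else "*"
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = loci$gene_id,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    strand = strand)
  gr$source <- source
  gr$type <- loci$type
  gr$ID <- if ("ID" %in% names(loci)) loci$ID else
    sprintf("locus%05d", seq_len(nrow(loci)))
  extra <- setdiff(names(loci), c(required, "strand", "ID"))
  for (col in extra)
    S4Vectors::mcols(gr)[[col]] <- as.character(loci[[col]])
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read back a GFF3 written by [writeLociGFF3()]
#'
#' @param path GFF3 path.
#' @return A data.frame with columns `gene_id`, `start`, `end`, `type`,
#'   `strand`, `ID` and any extra attribute columns (as character).
#' @export
readLociGFF3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L)
    return(data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), type = character(0),
                      strand = character(0), ID = character(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(
    gene_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    type = as.character(gr$type),
    strand = as.character(GenomicRanges::strand(gr)),
    ID = as.character(gr$ID),
    stringsAsFactors = FALSE)
  extra <- setdiff(colnames(S4Vectors::mcols(gr)),
                   c("source", "type", "score", "phase", "ID"))
  for (col in extra) out[[col]] <- as.character(S4Vectors::mcols(gr)[[col]])
  out
}

#' Read an orthology/paralogy table
#'
#' Three tab-separated columns: target gene id, comparator species,
#' comparator gene id.  Self-species rows (paralogs) are allowed.
#'
#' @param path TSV path.
#' @return A data.frame with columns `target_gene`, `comparator_species`,
#'   `comparator_gene`.
#' @export
readOrthologyTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    .stopf("orthology table must have 3 columns (target_gene, comparator_species, comparator_gene)")
  names(df)[1:3] <- c("target_gene", "comparator_species", "comparator_gene")
  df[, 1:3]
}
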