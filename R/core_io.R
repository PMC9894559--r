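# Readers/writers for the external formats used across the package, plus the
# shared coordinate conventions.  All internal coordinates are 0-based
# half-open on the forward strand; GFF3 (1-based closed) and BED (0-based
# half-open) are converted at the boundary.

VALID_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a genome record
#'
#' A genome record holds one (possibly circular) nucleotide sequence together
#' with its identity and host metadata.  Sequences are uppercase strings over
#' the alphabet A, C, G, T, N.  Circularity is a genome-level flag; features
#' that wrap the origin are represented as two annotation parts sharing a
#' `gene_id` rather than with `end < start`.
#'
#' @param genome_id Unique identifier string.
#' @param sequence Nucleotide string (case-insensitive; uppercased on input).
#' @param circular Logical, whether the replicon is circular.
#' @param supergroup Optional supergroup label (e.g. "A", "B", ... "S").
#' @param host_taxon,host_order Optional host metadata strings.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(genome_id, sequence, circular = FALSE,
                          supergroup = NA_character_,
                          host_taxon = NA_character_,
                          host_order = NA_character_) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("genome '", genome_id, "': sequence is empty")
  bad <- setdiff(unique(strsplit(sequence, "", fixed = TRUE)[[1]]), VALID_ALPHABET)
  if (length(bad) > 0L) {
    stop("genome '", genome_id, "': illegal character(s) in sequence: ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(genome_id = genome_id, sequence = sequence,
         circular = isTRUE(circular),
         supergroup = supergroup, host_taxon = host_taxon,
         host_order = host_order),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp%s%s\n", x$genome_id,
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) ", circular" else "",
              if (!is.na(x$supergroup)) paste0(", supergroup ", x$supergroup) else ""))
  invisible(x)
}

#' Genome length helper
#' @param genome A `genome_record`.
#' @return Integer sequence length.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

#' Reverse complement of a nucleotide string
#' @param sequence Character scalar over A,C,G,T,N.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

# ---- gene annotations -------------------------------------------------------

KNOWN_TAGS <- c("head", "baseplate", "tail", "fibre", "phage_linked",
                "cifA", "cifB",
                "bioA", "bioB", "bioC", "bioD", "bioF", "bioH",
                "transposase", "other")

#' Construct a gene annotation table
#'
#' Gene annotations live in an ordinary data frame with one row per gene part:
#' `genome_id`, `gene_id`, `start`, `end` (0-based half-open, forward strand),
#' `strand` ("+" or "-"), `family_id`, and `tags` (comma-joined labels).
#'
#' @param genome_id,gene_id Character vectors.
#' @param start,end Integer 0-based half-open coordinates, `start < end`.
#' @param strand Character vector of "+"/"-".
#' @param family_id Orthogroup labels (NA allowed).
#' @param tags Character vector of comma-joined tag labels ("" for none).
#' @return A `data.frame` of class `gene_annotations`.
#' @export
gene_annotations <- function(genome_id = character(), gene_id = character(),
                             start = integer(), end = integer(),
                             strand = character(),
                             family_id = NA_character_, tags = "") {
  n <- length(gene_id)
  df <- data.frame(genome_id = rep_len(as.character(genome_id), n),
                   gene_id = as.character(gene_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(as.character(strand), n),
                   family_id = rep_len(as.character(family_id), n),
                   tags = rep_len(as.character(tags), n),
                   stringsAsFactors = FALSE)
  validate_annotations(df)
}

validate_annotations <- function(df) {
  if (nrow(df) == 0L) {
    class(df) <- c("gene_annotations", class(df))
    return(df)
  }
  bad <- which(!(df$start >= 0L & df$start < df$end))
  if (length(bad) > 0L) {
    stop("invalid gene interval(s) (need 0 <= start < end) for gene(s): ",
         paste(unique(df$gene_id[bad]), collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) {
    bad <- unique(df$gene_id[!(df$strand %in% c("+", "-"))])
    stop("strand must be '+' or '-' (gene(s): ", paste(bad, collapse = ", "), ")")
  }
  if (!inherits(df, "gene_annotations")) class(df) <- c("gene_annotations", class(df))
  df
}

#' Does each gene carry a given tag?
#' @param annotations A `gene_annotations` data frame.
#' @param tag Tag label.
#' @return Logical vector along rows.
#' @export
has_tag <- function(annotations, tag) {
  vapply(strsplit(annotations$tags, ",", fixed = TRUE),
         function(tt) tag %in% tt, logical(1))
}

#' @rdname has_tag
#' @param tags Character vector of tag labels; a row matches if it carries any.
#' @export
has_any_tag <- function(annotations, tags) {
  vapply(strsplit(annotations$tags, ",", fixed = TRUE),
         function(tt) any(tags %in% tt), logical(1))
}

# ---- FASTA ------------------------------------------------------------------

#' Read genome records from a FASTA file
#'
#' Sequences are uppercased and restricted to the alphabet A,C,G,T,N.  The
#' description line may carry `key=value` tokens (`circular`, `supergroup`,
#' `host_taxon`, `host_order`) which populate the record metadata.
#'
#' @param path FASTA file path.
#' @return List of `genome_record`s in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file has no records: ", path)
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    toks <- strsplit(headers[i], "[ \t]+")[[1]]
    id <- toks[1]
    kv <- grep("=", toks[-1], fixed = TRUE, value = TRUE)
    meta <- list(circular = "false", supergroup = NA_character_,
                 host_taxon = NA_character_, host_order = NA_character_)
    for (t in kv) {
      p <- strsplit(t, "=", fixed = TRUE)[[1]]
      if (length(p) == 2L && p[1] %in% names(meta)) meta[[p[1]]] <- p[2]
    }
    genome_record(id, as.character(set[[i]]),
                  circular = tolower(meta$circular) %in% c("true", "1", "yes"),
                  supergroup = meta$supergroup,
                  host_taxon = meta$host_taxon, host_order = meta$host_order)
  })
}

#' Write genome records to a FASTA file
#' @param genomes List of `genome_record`s.
#' @param path Output path.
#' @param width Line wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(genomes, path, width = 80L) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  if (anyDuplicated(ids)) stop("duplicate genome_id in collection")
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    hdr <- paste0(">", g$genome_id, " circular=", tolower(g$circular))
    if (!is.na(g$supergroup)) hdr <- paste0(hdr, " supergroup=", g$supergroup)
    if (!is.na(g$host_taxon)) hdr <- paste0(hdr, " host_taxon=", g$host_taxon)
    if (!is.na(g$host_order)) hdr <- paste0(hdr, " host_order=", g$host_order)
    writeLines(hdr, con)
    L <- nchar(g$sequence)
    starts <- seq(1L, L, by = width)
    writeLines(substring(g$sequence, starts, pmin(starts + width - 1L, L)), con)
  }
  invisible(path)
}

# ---- GFF3 -------------------------------------------------------------------

#' Read gene annotations from a GFF3-style file
#'
#' Expects the 9-column GFF3 dialect written by [write_gff_annotations()]:
#' 1-based closed coordinates (converted to internal 0-based half-open),
#' mandatory strand, and attributes carrying `ID`, optionally `family` and
#' `tags` (comma-separated).  Unknown tag labels are kept verbatim; a missing
#' tag list yields `"other"`.
#'
#' @param path GFF3 file path.
#' @return A `gene_annotations` data frame.
#' @export
read_gff_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(lines))
  rows <- lapply(keep, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) stop("GFF parse error at line ", i, ": expected 9 columns, got ",
                              length(f))
    start1 <- suppressWarnings(as.integer(f[4])); end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1)) stop("GFF parse error at line ", i, ": non-numeric coordinates")
    if (end1 < start1) stop("GFF parse error at line ", i, ": end < start")
    if (!(f[7] %in% c("+", "-"))) stop("GFF parse error at line ", i,
                                       ": strand must be '+' or '-', got '", f[7], "'")
    attrs <- strsplit(f[9], ";", fixed = TRUE)[[1]]
    kv <- strsplit(attrs, "=", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1)
    vals <- vapply(kv, function(p) if (length(p) >= 2) p[2] else "", character(1))
    att <- stats::setNames(vals, keys)
    id <- if ("ID" %in% keys) att[["ID"]] else paste0("gene", i)
    fam <- if ("family" %in% keys && nzchar(att[["family"]])) att[["family"]] else NA_character_
    tags <- if ("tags" %in% keys && nzchar(att[["tags"]])) att[["tags"]] else "other"
    data.frame(genome_id = f[1], gene_id = id,
               start = start1 - 1L, end = end1,
               strand = f[7], family_id = fam, tags = tags,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(genome_id = character(), gene_id = character(), start = integer(),
               end = integer(), strand = character(), family_id = character(),
               tags = character(), stringsAsFactors = FALSE)
  validate_annotations(df)
}

#' Write gene annotations to a GFF3-style file
#' @param annotations A `gene_annotations` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff_annotations <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(annotations) > 0L) {
    att <- paste0("ID=", annotations$gene_id,
                  ifelse(is.na(annotations$family_id), "",
                         paste0(";family=", annotations$family_id)),
                  ifelse(nzchar(annotations$tags),
                         paste0(";tags=", annotations$tags), ""))
    writeLines(paste(annotations$genome_id, "endosym", "gene",
                     annotations$start + 1L, annotations$end, ".",
                     annotations$strand, ".", att, sep = "\t"), con)
  }
  invisible(path)
}

# ---- PAF-like read alignments ----------------------------------------------

#' Read a PAF-like read-to-contig alignment table
#'
#' Six tab-separated columns: read_id, contig_id, contig_start, contig_end
#' (0-based half-open), mapq, read_class (endosymbiont / host / unknown /
#' nuwt).  CIGAR strings and the remaining PAF columns are out of scope.
#'
#' @param path TSV path.
#' @return A data frame of read alignments.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 6L)) stop("alignment parse error at row ", which(nc != 6L)[1],
                          ": expected 6 columns, got ", nc[which(nc != 6L)[1]])
  df <- data.frame(read_id = vapply(parts, `[`, "", 1),
                   contig_id = vapply(parts, `[`, "", 2),
                   contig_start = as.integer(vapply(parts, `[`, "", 3)),
                   contig_end = as.integer(vapply(parts, `[`, "", 4)),
                   mapq = as.integer(vapply(parts, `[`, "", 5)),
                   read_class = vapply(parts, `[`, "", 6),
                   stringsAsFactors = FALSE)
  if (any(df$contig_start >= df$contig_end))
    stop("alignment parse error: contig_start >= contig_end at row ",
         which(df$contig_start >= df$contig_end)[1])
  df
}

#' @rdname read_alignments
#' @param alignments Data frame as returned by [read_alignments()].
#' @export
write_alignments <- function(alignments, path) {
  utils::write.table(alignments[, c("read_id", "contig_id", "contig_start",
                                    "contig_end", "mapq", "read_class")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- BED --------------------------------------------------------------------

#' Write genomic regions to a BED file (0-based half-open)
#' @param regions Data frame with columns genome_id, start, end and optionally
#'   name and score.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  name <- if ("name" %in% names(regions)) regions$name else
    paste0("region", seq_len(nrow(regions)))
  df <- data.frame(regions$genome_id, regions$start, regions$end, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of regions
#' @param path BED path.
#' @return Data frame with genome_id, start, end, name.
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(genome_id = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc < 3L)) stop("BED parse error at row ", which(nc < 3L)[1],
                         ": expected >= 3 columns")
  data.frame(genome_id = vapply(parts, `[`, "", 1),
             start = as.integer(vapply(parts, `[`, "", 2)),
             end = as.integer(vapply(parts, `[`, "", 3)),
             name = vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_, ""),
             stringsAsFactors = FALSE)
}

# ---- newick -----------------------------------------------------------------

#' Read / write newick trees (thin wrappers around \pkg{ape})
#' @param path Newick file path.
#' @return For `read_tree`, an \pkg{ape} `phylo` object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ape::read.tree(path)
}

#' @rdname read_tree
#' @param tree An \pkg{ape} `phylo` object.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# ---- family matrix ----------------------------------------------------------

#' Read / write an orthogroup copy-number matrix (TSV)
#'
#' Rows are families, columns are genomes; the first column holds family ids.
#'
#' @param path TSV path.
#' @return Integer matrix with family rownames and genome colnames.
#' @export
read_family_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("family matrix must have a family column plus >= 1 genome column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  if (any(is.na(m))) stop("family matrix contains non-integer entries")
  m
}

#' @rdname read_family_matrix
#' @param matrix Integer matrix (families x genomes).
#' @export
write_family_matrix <- function(matrix, path) {
  df <- data.frame(family_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
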