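# shared fixture builders; everything is generated in code at test time

random_seq <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

make_genome <- function(n = 50000L, seed = 1, circular = TRUE, id = "gx") {
  genome_record(id, random_seq(n, seed), circular = circular)
}

# substitute a given fraction of sites uniformly at random
substitute_seq <- function(sequence, fraction, seed = 1) {
  set.seed(seed)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  k <- round(length(chars) * fraction)
  idx <- sample(length(chars), k)
  chars[idx] <- vapply(chars[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  paste(chars, collapse = "")
}

# a hit table row for the marker screen
hit_row <- function(evalue = 1e-160, len = 1500, id = 95,
                    lineage = "Bacteria;Proteobacteria;Alphaproteobacteria;Rickettsiales;Anaplasmataceae;Wolbachia;Wolbachia_pipientis",
                    bitscore = 1000, target = "t1") {
  data.frame(query_id = "q", target_id = target, evalue = evalue,
             aligned_length = len, pct_identity = id, bitscore = bitscore,
             lineage = lineage, stringsAsFactors = FALSE)
}

hit_table <- function(n, lineages, bitscores = NULL) {
  do.call(rbind, lapply(seq_len(n), function(i)
    hit_row(lineage = lineages[i],
            bitscore = if (is.null(bitscores)) 1000 - i else bitscores[i],
            target = sprintf("t%03d", i))))
}

lineage_to <- function(..., depth = NULL) paste(c(...), collapse = ";")

# simple annotation builder: genes laid out consecutively, length 100, gap 10
ann_track <- function(tags, genome_id = "g1", families = NULL) {
  n <- length(tags)
  starts <- (seq_len(n) - 1L) * 110L
  gene_annotations(genome_id = genome_id,
                   gene_id = sprintf("%s_g%03d", genome_id, seq_len(n)),
                   start = starts, end = starts + 100L,
                   strand = "+",
                   family_id = if (is.null(families))
                     sprintf("fam%03d", seq_len(n)) else families,
                   tags = tags)
}

# independent closed-form rarefaction expectations (hypergeometric identity)
rarefaction_closed_form <- function(matrix, exclude_novel = TRUE) {
  P <- matrix > 0L
  if (exclude_novel) P <- P[rowSums(P) != 1L, , drop = FALSE]
  N <- ncol(P); nf <- rowSums(P)
  list(pan = vapply(seq_len(N), function(k)
         sum(1 - choose(N - nf, k) / choose(N, k)), numeric(1)),
       core = vapply(seq_len(N), function(k)
         sum(choose(nf, k) / choose(N, k)), numeric(1)))
}
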