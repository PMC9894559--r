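# Gap-tolerant WO-prophage detection: runs of phage-linked genes with at
# most `max_gap_genes` other genes in between, completeness calls from module
# inventories, span fractions, and EAM cargo extraction.

PHAGE_CORE_MODULES <- c("head", "baseplate", "tail", "fibre")
MODULE_EXPECTED <- c(head = 6L, baseplate = 8L, tail = 6L, fibre = 6L)
COMPLETENESS_MIN <- c(head = 5L, baseplate = 7L, tail = 5L, fibre = 5L)

#' Scan annotations for prophage regions
#'
#' Genes are walked in genome order (circular order honoured for circular
#' genomes: runs are joined across the origin before maximality is decided).
#' A run is a maximal stretch of phage-linked genes (any gene tagged with a
#' core module or `phage_linked`) in which consecutive phage-linked genes are
#' separated by at most `max_gap_genes` non-phage genes.  A run is emitted as
#' a region iff it contains at least one gene from a core module (head,
#' baseplate, tail, fibre); `phage_linked` tags may extend runs but cannot
#' seed a region.  The region span runs from the start of the first to the
#' end of the last phage-linked gene; spans that wrap the origin are reported
#' with `end > genome length`.
#'
#' @param annotations `gene_annotations` for one genome, ordered by start.
#' @param max_gap_genes Maximum number of intervening non-phage genes.
#' @param circular Is the genome circular? (Default TRUE.)
#' @param genome_len Genome length (required when `circular`).
#' @return List of `prophage_region` objects: genome_id, region_id, span
#'   (c(start, end), 0-based half-open, end may exceed genome length for
#'   wrapped regions), gene_ids, inventory (per-module distinct family
#'   counts), complete, cargo_gene_ids.
#' @export
scan_prophage <- function(annotations, max_gap_genes = 5L, circular = TRUE,
                          genome_len = NULL) {
  if (nrow(annotations) == 0L) return(list())
  if (length(unique(annotations$genome_id)) != 1L)
    stop("scan_prophage expects annotations for a single genome")
  if (is.unsorted(annotations$start))
    stop("annotations must be ordered by start")
  if (circular && is.null(genome_len))
    stop("genome_len required for circular scanning")

  ann <- annotations
  n <- nrow(ann)
  is_phage <- has_any_tag(ann, c(PHAGE_CORE_MODULES, "phage_linked"))
  phage_idx <- which(is_phage)
  if (length(phage_idx) == 0L) return(list())

  # group consecutive phage genes allowing <= max_gap_genes others between
  gaps <- diff(phage_idx) - 1L
  newrun <- c(TRUE, gaps > max_gap_genes)
  run_id <- cumsum(newrun)
  runs <- split(phage_idx, run_id)

  # circular closure: join the last run to the first if the gap across the
  # origin is small enough (count non-phage genes after the last phage gene
  # plus those before the first)
  wrapped <- FALSE
  if (circular && length(runs) > 1L) {
    gap_around <- (n - max(phage_idx)) + (min(phage_idx) - 1L)
    if (gap_around <= max_gap_genes) {
      runs[[1L]] <- c(runs[[length(runs)]], runs[[1L]])
      runs[[length(runs)]] <- NULL
      wrapped <- TRUE
    }
  }

  gid <- ann$genome_id[1]
  out <- list()
  for (ri in seq_along(runs)) {
    idx <- runs[[ri]]
    genes <- ann[idx, , drop = FALSE]
    core_mask <- has_any_tag(genes, PHAGE_CORE_MODULES)
    if (!any(core_mask)) next
    # all genes (phage and intervening) within the run's index range
    if (ri == 1L && wrapped) {
      cut <- which(diff(idx) < 0L)  # where indices wrap past the origin
      firstpart <- idx[seq_len(cut)]
      lastpart <- idx[seq(cut + 1L, length(idx))]
      inside <- c(seq(min(firstpart), n), seq(1L, max(lastpart)))
      span <- c(ann$start[min(firstpart)],
                ann$end[max(lastpart)] + genome_len)
    } else {
      inside <- seq(min(idx), max(idx))
      span <- c(ann$start[min(idx)], ann$end[max(idx)])
    }
    region_genes <- ann[inside, , drop = FALSE]
    inv <- vapply(PHAGE_CORE_MODULES, function(m) {
      g <- region_genes[has_tag(region_genes, m), , drop = FALSE]
      length(unique(g$family_id))
    }, integer(1))
    structural <- has_any_tag(region_genes, PHAGE_CORE_MODULES)
    region <- structure(list(
      genome_id = gid,
      region_id = paste0(gid, "_wo", length(out) + 1L),
      span = span,
      gene_ids = region_genes$gene_id,
      inventory = inv,
      complete = all(inv >= COMPLETENESS_MIN[PHAGE_CORE_MODULES]),
      cargo_gene_ids = region_genes$gene_id[!structural]),
      class = "prophage_region")
    out[[length(out) + 1L]] <- region
  }
  out
}

#' Completeness call for a prophage region
#'
#' A region is putatively complete iff its module inventory reaches at least
#' 5 of 6 head, 7 of 8 baseplate, 5 of 6 fibre and 5 of 6 tail distinct
#' family slots (duplicated genes count once).
#'
#' @param region A `prophage_region`, or a named vector of module counts.
#' @return Logical.
#' @export
completeness_call <- function(region) {
  inv <- if (inherits(region, "prophage_region")) region$inventory else region
  all(inv[PHAGE_CORE_MODULES] >= COMPLETENESS_MIN[PHAGE_CORE_MODULES])
}

#' Fraction of a genome covered by prophage regions
#'
#' @param genome A `genome_record` (or integer genome length).
#' @param regions List of `prophage_region`s (non-overlapping; wrapped spans
#'   are counted once).
#' @return Numeric fraction in [0,1].
#' @export
prophage_span_fraction <- function(genome, regions) {
  L <- if (inherits(genome, "genome_record")) genome_length(genome) else
    as.integer(genome)
  if (length(regions) == 0L) return(0)
  spans <- t(vapply(regions, function(r) r$span, numeric(2)))
  # unwrap to linear intervals modulo L for the overlap check
  iv <- lapply(seq_len(nrow(spans)), function(i) {
    s <- spans[i, 1]; e <- spans[i, 2]
    if (e <= L) list(c(s, e)) else list(c(s, L), c(0, e - L))
  })
  iv <- do.call(rbind, lapply(unlist(iv, recursive = FALSE), rbind))
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1, 1] < iv[-nrow(iv), 2]))
    stop("prophage regions overlap")
  sum(spans[, 2] - spans[, 1]) / L
}

#' Extract EAM cargo genes of a region
#'
#' Cargo genes are genes inside the region span that carry no structural
#' module tag (CifA/CifB, ankyrin, transposase and untagged genes all
#' qualify).  A gene is inside iff its start lies within the span.
#'
#' @param region A `prophage_region`.
#' @param annotations `gene_annotations` for the region's genome.
#' @return Character vector of cargo gene ids.
#' @export
eam_cargo <- function(region, annotations) {
  ann <- annotations[annotations$genome_id == region$genome_id, , drop = FALSE]
  s <- region$span[1]; e <- region$span[2]
  inside <- ann$start >= s & ann$start < e
  genes <- ann[inside, , drop = FALSE]
  structural <- has_any_tag(genes, PHAGE_CORE_MODULES)
  genes$gene_id[!structural]
}
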