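#' Parse lineage-barcode reads
#'
#' Finds the first window within Hamming distance 1 of the anchor 7-mer
#' \code{TAGACAT} (leftmost match; the anchor and everything before it is
#' trimmed), takes the following 48 bp, and validates the staggered
#' invariant 2-mers. Reads whose UMI is entirely G are discarded. Every
#' read receives exactly one status:
#' \code{accepted}, \code{NO_ANCHOR}, \code{SHORT}, \code{POLYG_UMI} or
#' \code{INVARIANT_FAIL}.
#'
#' @param sequences Character vector of read sequences (A/C/G/T/N).
#' @param umis Character vector of UMIs, same length.
#' @param template A [barcode_template()].
#' @param max_anchor_mismatch Maximum mismatches allowed in the anchor.
#' @return A data.frame with columns \code{barcode} (48-mer or NA) and
#'   \code{status} (factor with the five levels above).
#' @export
parse_barcode_reads <- function(sequences, umis,
                                template = barcode_template(),
                                max_anchor_mismatch = 1L) {
  stopifnot(length(sequences) == length(umis))
  n <- length(sequences)
  status <- rep("accepted", n)
  barcode <- rep(NA_character_, n)
  pos <- find_anchor(sequences, template$anchor, max_anchor_mismatch)
  status[pos == 0L] <- "NO_ANCHOR"
  start <- pos + nchar(template$anchor)      # first base after the anchor
  short <- pos > 0L & nchar(sequences) - start + 1L < template$width
  status[short] <- "SHORT"
  polyg <- status == "accepted" & grepl("^G+$", umis)
  status[polyg] <- "POLYG_UMI"
  ok <- status == "accepted"
  if (any(ok)) {
    bc <- substr(sequences[ok], start[ok], start[ok] + template$width - 1L)
    valid <- rep(TRUE, length(bc))
    for (k in seq_along(template$stagger)) {
      off <- template$invariant_offsets[k]       # 0-based
      valid <- valid & substr(bc, off + 1L, off + 2L) == template$stagger[k]
    }
    barcode[ok][valid] <- bc[valid]
    status[ok][!valid] <- "INVARIANT_FAIL"
  }
  data.frame(barcode = barcode,
             status = factor(status, levels = c("accepted", "NO_ANCHOR",
                                                "SHORT", "POLYG_UMI",
                                                "INVARIANT_FAIL")),
             stringsAsFactors = FALSE)
}

#' Count reads per cell-UMI-barcode triple
#'
#' @param cells,umis,barcodes Parallel vectors, one entry per accepted read.
#' @return A data.frame (cell, umi, barcode, reads) with one row per
#'   distinct triple.
#' @export
count_triples <- function(cells, umis, barcodes) {
  stopifnot(length(cells) == length(umis), length(umis) == length(barcodes))
  key <- paste(cells, umis, barcodes, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  data.frame(cell = vapply(parts, `[`, "", 1L),
             umi = vapply(parts, `[`, "", 2L),
             barcode = vapply(parts, `[`, "", 3L),
             reads = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter triples by read support
#'
#' Triples supported by fewer than \code{min_reads} reads are removed;
#' the default of 5 removes base-call errors surviving as rare variants.
#'
#' @param triples A data.frame as returned by [count_triples()].
#' @param min_reads Minimum read count (inclusive).
#' @return The retained rows.
#' @export
filter_support <- function(triples, min_reads = 5L) {
  stopifnot(all(triples$reads >= 1L))
  triples[threshold_at_least(triples$reads, min_reads), , drop = FALSE]
}

#' Two-stage Levenshtein collapse of barcode sequences
#'
#' Stage 1: each barcode is assigned to the most abundant barcode within
#' edit distance 4 of it (itself included; ties broken lexicographically by
#' sequence). Stage 2: among the resulting representatives, a single pass
#' in decreasing abundance collapses any representative within edit
#' distance 2 of an already-accepted, more abundant representative. The
#' final consensus set is therefore pairwise separated by edit distance
#' greater than 2, which is asserted.
#'
#' @param abundance Named numeric vector: barcode sequence to abundance
#'   (e.g. total supporting reads or triples).
#' @return A list with \code{consensus} (character vector) and \code{map}
#'   (named character vector, every input barcode to its consensus).
#' @export
collapse_barcodes <- function(abundance) {
  if (!length(abundance)) return(list(consensus = character(0),
                                      map = character(0)))
  stopifnot(!is.null(names(abundance)), all(abundance > 0))
  bc <- names(abundance)
  d <- utils::adist(bc)
  # stage 1: most abundant within distance 4 (ties: lexicographically first)
  stage1 <- character(length(bc))
  for (i in seq_along(bc)) {
    cand <- which(d[i, ] <= 4)
    best <- cand[order(-abundance[cand], bc[cand])][1L]
    stage1[i] <- bc[best]
  }
  reps <- unique(stage1)
  rep_ab <- vapply(reps, function(r) abundance[[r]], numeric(1))
  ord <- order(-rep_ab, reps)
  consensus <- character(0)
  stage2 <- stats::setNames(character(length(reps)), reps)
  for (r in reps[ord]) {
    hit <- if (length(consensus))
      which(utils::adist(r, consensus)[1L, ] <= 2)[1L] else NA_integer_
    if (!is.na(hit)) {
      stage2[r] <- consensus[hit]
    } else {
      consensus <- c(consensus, r)
      stage2[r] <- r
    }
  }
  if (length(consensus) > 1L) {
    dc <- utils::adist(consensus)
    diag(dc) <- Inf
    if (min(dc) <= 2)
      stop("consensus barcodes closer than edit distance 3 after collapse")
  }
  map <- stats::setNames(stage2[stage1], bc)
  list(consensus = consensus, map = map)
}

#' Assign cells to clones and clones to samples
#'
#' Each cell is assigned to the clone (consensus barcode) supported by the
#' plurality of its UMIs; cells with a tied plurality are excluded as
#' ambiguous. Clones with fewer than \code{min_cells} cells are dropped.
#' Each retained clone is assigned to the sample contributing the most
#' cells, with the majority fraction reported as purity.
#'
#' @param triples Support-filtered triples ([filter_support()]).
#' @param map Barcode-to-consensus map from [collapse_barcodes()].
#' @param cell_sample Optional named character vector, cell to sample.
#' @param min_cells Minimum cells per retained clone.
#' @return A list of class \code{"clone_map"}: \code{cell_to_clone},
#'   \code{clone_to_sample}, \code{clone_sizes}, \code{clone_purity},
#'   \code{consensus_barcodes} (clone id to 48-mer) and
#'   \code{ambiguous_cells}.
#' @export
assign_clones <- function(triples, map, cell_sample = NULL, min_cells = 5L) {
  if (any(!triples$barcode %in% names(map)))
    stop("every triple barcode needs a consensus assignment")
  cons <- map[triples$barcode]
  # distinct UMIs supporting each (cell, consensus)
  key <- paste(triples$cell, cons, triples$umi, sep = "\r")
  dd <- unique(data.frame(cell = triples$cell, cons = cons,
                          umi = triples$umi, stringsAsFactors = FALSE))
  support <- stats::aggregate(list(umis = dd$umi),
                              by = list(cell = dd$cell, cons = dd$cons),
                              FUN = length)
  ambiguous <- character(0)
  assign <- list()
  for (cell in unique(support$cell)) {
    rows <- support[support$cell == cell, , drop = FALSE]
    top <- max(rows$umis)
    winners <- rows$cons[rows$umis == top]
    if (length(winners) > 1L) ambiguous <- c(ambiguous, cell)
    else assign[[cell]] <- winners
  }
  cell_bc <- unlist(assign)
  if (!length(cell_bc))
    return(structure(list(cell_to_clone = character(0),
                          clone_to_sample = character(0),
                          clone_sizes = integer(0),
                          clone_purity = numeric(0),
                          consensus_barcodes = character(0),
                          ambiguous_cells = ambiguous),
                     class = "clone_map"))
  sizes <- table(cell_bc)
  keep <- names(sizes)[sizes >= min_cells]
  cell_bc <- cell_bc[cell_bc %in% keep]
  # clone ids ordered by decreasing size, then barcode
  keep <- keep[order(-as.integer(sizes[keep]), keep)]
  clone_ids <- stats::setNames(sprintf("clone_%03d", seq_along(keep)), keep)
  cell_to_clone <- stats::setNames(clone_ids[cell_bc], names(cell_bc))
  clone_sizes <- table(cell_to_clone)
  clone_sizes <- stats::setNames(as.integer(clone_sizes), names(clone_sizes))
  clone_to_sample <- stats::setNames(rep(NA_character_, length(keep)),
                                     clone_ids)
  purity <- stats::setNames(rep(NA_real_, length(keep)), clone_ids)
  if (!is.null(cell_sample)) {
    for (cl in clone_ids) {
      cells <- names(cell_to_clone)[cell_to_clone == cl]
      samp <- table(cell_sample[cells])
      clone_to_sample[cl] <- names(samp)[which.max(samp)]
      purity[cl] <- max(samp) / sum(samp)
    }
  }
  structure(list(cell_to_clone = cell_to_clone,
                 clone_to_sample = clone_to_sample,
                 clone_sizes = clone_sizes,
                 clone_purity = purity,
                 consensus_barcodes = stats::setNames(keep, clone_ids),
                 ambiguous_cells = ambiguous),
            class = "clone_map")
}

#' Full clone-calling pipeline from barcode reads
#'
#' Parses reads, counts and filters cell-UMI-barcode triples, collapses
#' sequencing errors into consensus barcodes, and assigns cells to clones
#' (and clones to samples when sample labels are given).
#'
#' @param reads Data.frame with columns \code{cell}, \code{umi},
#'   \code{sequence} (one row per read), e.g. from
#'   [simulate_barcode_reads()] or [read_barcode_fastq()].
#' @param cell_sample Optional named character vector, cell to sample.
#' @param min_reads Minimum reads per triple.
#' @param min_cells Minimum cells per clone.
#' @param template A [barcode_template()].
#' @return A \code{"clone_map"} (see [assign_clones()]) with an extra
#'   \code{qc} element: parser status counts, triple counts before/after
#'   support filtering, and the number of consensus barcodes.
#' @export
call_clones <- function(reads, cell_sample = NULL, min_reads = 5L,
                        min_cells = 5L, template = barcode_template()) {
  parsed <- parse_barcode_reads(reads$sequence, reads$umi, template)
  qc <- list(status = table(parsed$status))
  ok <- parsed$status == "accepted"
  triples <- count_triples(reads$cell[ok], reads$umi[ok], parsed$barcode[ok])
  qc$n_triples <- nrow(triples)
  triples <- filter_support(triples, min_reads)
  qc$n_triples_supported <- nrow(triples)
  if (!nrow(triples)) stop("no triples survive the read-support filter")
  ab <- tapply(triples$reads, triples$barcode, sum)
  collapsed <- collapse_barcodes(stats::setNames(as.numeric(ab), names(ab)))
  qc$n_consensus <- length(collapsed$consensus)
  out <- assign_clones(triples, collapsed$map, cell_sample, min_cells)
  out$qc <- qc
  out
}

#' @export
print.clone_map <- function(x, ...) {
  cat("Clone map:", length(unique(x$cell_to_clone)), "clones,",
      length(x$cell_to_clone), "assigned cells,",
      length(x$ambiguous_cells), "ambiguous cells\n")
  if (length(x$clone_sizes)) {
    cat("Clone sizes: ")
    print(summary(as.integer(x$clone_sizes)))
  }
  invisible(x)
}

#' Write and read barcode reads as FASTQ
#'
#' Reads are written as 4-line FASTQ records named
#' \code{cell:umi:serial}; [read_barcode_fastq()] recovers the
#' (cell, umi, sequence) table. A \code{.gz} path is compressed
#' transparently.
#'
#' @param reads Data.frame with \code{cell}, \code{umi}, \code{sequence}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_barcode_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  ids <- sprintf("@%s:%s:%d", reads$cell, reads$umi, seq_len(nrow(reads)))
  writeLines(rbind(ids, reads$sequence, "+",
                   strrep("I", nchar(reads$sequence))), con)
  invisible(path)
}

#' @rdname write_barcode_fastq
#' @export
read_barcode_fastq <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  parts <- strsplit(sub("^@", "", ids), ":", fixed = TRUE)
  data.frame(cell = vapply(parts, `[`, "", 1L),
             umi = vapply(parts, `[`, "", 2L),
             sequence = seqs, stringsAsFactors = FALSE)
}
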