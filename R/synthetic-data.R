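#' Simulation configuration for clone-structured single-cell scores
#'
#' Bundles the parameters shared by the synthetic-data generators and
#' validates them once. The defaults describe the geometry used throughout
#' the package's tests: 50 clones of 20 cells, 500 scored features of which
#' 50 carry a planted clonal variance component.
#'
#' @param seed Master integer seed. Every generator derives its own
#'   sub-stream from it, so identical configurations reproduce identical
#'   outputs byte-for-byte.
#' @param n_cells,n_clones,n_features,n_heritable Problem size. Heritable
#'   features carry a clone-level random effect; the remaining features are
#'   pure noise.
#' @param clone_sd Standard deviation of the planted per-clone effect on
#'   heritable features. Zero gives a null dataset.
#' @param noise_sd Within-clone (cell-level) noise standard deviation.
#' @param conditions Named numeric vector of per-condition mean shifts added
#'   to heritable-feature scores. Clones are split across conditions in
#'   order; the last condition plays the role of the case/recovered group.
#' @param frac_high Fraction of case-condition clones given an extra
#'   \code{high_shift} on the signature (first heritable) feature, emulating
#'   an exceptional high-memory clone subpopulation.
#' @param high_shift Score shift applied to high clones.
#' @param noise_ratio Multiplier on \code{noise_sd} for case-condition
#'   cells; values > 1 plant a within-clone variance difference between
#'   conditions.
#' @param error_rate Per-base substitution probability for barcode reads.
#' @param depth_meanlog,depth_sdlog Log-normal parameters for per-cell
#'   total counts.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L, n_cells = 1000L, n_clones = 50L,
                       n_features = 500L, n_heritable = min(50L, n_features),
                       clone_sd = 1, noise_sd = 1,
                       conditions = c(control = 0, colitis = 0),
                       frac_high = 0, high_shift = 2.5, noise_ratio = 1,
                       error_rate = 0, depth_meanlog = log(5000),
                       depth_sdlog = 0.5) {
  cfg <- list(seed = as.integer(seed), n_cells = as.integer(n_cells),
              n_clones = as.integer(n_clones),
              n_features = as.integer(n_features),
              n_heritable = as.integer(n_heritable),
              clone_sd = clone_sd, noise_sd = noise_sd,
              conditions = conditions, frac_high = frac_high,
              high_shift = high_shift, noise_ratio = noise_ratio,
              error_rate = error_rate, depth_meanlog = depth_meanlog,
              depth_sdlog = depth_sdlog)
  if (cfg$n_cells < 1L || cfg$n_clones < 1L || cfg$n_features < 1L)
    stop("counts must be positive")
  if (cfg$n_clones > cfg$n_cells)
    stop("n_clones must not exceed n_cells")
  if (cfg$n_heritable < 0L || cfg$n_heritable > cfg$n_features)
    stop("n_heritable must lie in [0, n_features]")
  if (cfg$clone_sd < 0 || cfg$noise_sd <= 0)
    stop("clone_sd must be >= 0 and noise_sd > 0")
  if (cfg$frac_high < 0 || cfg$frac_high > 1)
    stop("frac_high must lie in [0, 1]")
  if (cfg$error_rate < 0 || cfg$error_rate >= 1)
    stop("error_rate must lie in [0, 1)")
  if (is.null(names(cfg$conditions)) || length(cfg$conditions) < 1L)
    stop("conditions must be a named numeric vector of mean shifts")
  class(cfg) <- "sim_config"
  cfg
}

#' The invariant structure of the 48-bp expressed lineage barcode
#'
#' The barcode cassette interleaves eight blocks of four random bases with
#' eight fixed 2-mers (CT, AC, TC, GT, TG, CA, AT, GC), giving the layout
#' \code{NNNNCTNNNNACNNNNTCNNNNGTNNNNTGNNNNCANNNNATNNNNGC}. The fixed
#' 2-mers sit at 0-based offsets 4, 10, 16, 22, 28, 34, 40, 46 and are used
#' to reject off-target PCR products during parsing. The cassette is
#' preceded in the read by the anchor 7-mer \code{TAGACAT}.
#'
#' @return A list of class \code{"barcode_template"} carrying the anchor,
#'   the stagger 2-mers with their offsets, the random-base offsets, the
#'   barcode width (48) and the UMI length (10).
#' @export
barcode_template <- function() {
  stagger <- c("CT", "AC", "TC", "GT", "TG", "CA", "AT", "GC")
  invariant_offsets <- 4L + 6L * (0:7)          # 0-based
  random_offsets <- as.vector(outer(0:3, 6L * (0:7), "+"))
  structure(list(anchor = "TAGACAT", stagger = stagger,
                 invariant_offsets = invariant_offsets,
                 random_offsets = sort(random_offsets),
                 width = 48L, umi_length = 10L),
            class = "barcode_template")
}

#' Render 48-bp barcodes from 32 random bases
#'
#' @param fill Character vector of 32-base strings (the N positions).
#' @param template A [barcode_template()].
#' @return Character vector of 48-bp barcodes obeying the stagger layout.
#' @export
render_barcode <- function(fill, template = barcode_template()) {
  stopifnot(all(nchar(fill) == 32L))
  vapply(fill, function(f) {
    blocks <- substring(f, seq(1L, 32L, by = 4L), seq(4L, 32L, by = 4L))
    paste0(paste0(blocks, template$stagger), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Sample well-separated clone barcodes
#'
#' Draws one 48-bp barcode per clone by rejection sampling until all
#' pairwise Levenshtein distances exceed \code{min_dist}. Well-separated
#' founder barcodes guarantee that the distance-4 error collapse cannot
#' merge distinct clones.
#'
#' @param n_clones Number of barcodes.
#' @param min_dist Minimum pairwise Levenshtein distance (exclusive bound;
#'   retained barcodes satisfy distance > \code{min_dist}).
#' @param template A [barcode_template()].
#' @param seed Integer seed.
#' @return Character vector of barcodes named \code{clone_01} etc.
#' @export
simulate_clone_barcodes <- function(n_clones, min_dist = 8L,
                                    template = barcode_template(),
                                    seed = 1L) {
  with_seed(seed, {
    bc <- render_barcode(random_dna(n_clones, 32L), template)
    for (iter in 1:200) {
      d <- utils::adist(bc)
      diag(d) <- Inf
      bad <- which(apply(d, 1L, min) <= min_dist)
      if (!length(bad)) break
      bc[bad] <- render_barcode(random_dna(length(bad), 32L), template)
    }
    if (length(bad <- which(apply(`diag<-`(utils::adist(bc), Inf), 1, min) <= min_dist)))
      stop("could not separate clone barcodes; reduce n_clones or min_dist")
    names(bc) <- sprintf("clone_%02d", seq_len(n_clones))
    bc
  })
}

#' Simulate clone-structured per-cell feature scores
#'
#' Each cell's score on a heritable feature is the sum of a clone-level
#' effect (scale \code{clone_sd}), its condition's mean shift and cell-level
#' noise; null features carry noise only. A configurable fraction of
#' case-condition clones receives an extra shift on the first heritable
#' (signature) feature, emulating the exceptional high-memory clones.
#'
#' @param config A [sim_config()].
#' @return A list of class \code{"sim_clonal_scores"} with elements
#'   \code{scores} (cells x features), \code{clone} and \code{condition}
#'   (named per-cell labels) and \code{truth} (planted heritable features,
#'   clone effects, high clones and per-clone conditions).
#' @export
simulate_clonal_scores <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_cells; nc <- config$n_clones; nf <- config$n_features
    cells <- sprintf("cell_%05d", seq_len(n))
    clones <- sprintf("clone_%02d", seq_len(nc))
    feats <- sprintf("feature_%04d", seq_len(nf))
    # round-robin assignment guarantees every clone has >= 1 cell
    clone <- sample(rep_len(clones, n))
    names(clone) <- cells
    # clones split across conditions in contiguous blocks
    cond_names <- names(config$conditions)
    clone_cond <- rep(cond_names, length.out = 0L)
    sizes <- diff(round(seq(0, nc, length.out = length(cond_names) + 1L)))
    clone_cond <- rep(cond_names, times = sizes)
    names(clone_cond) <- clones
    condition <- clone_cond[clone]
    names(condition) <- cells

    heritable <- feats[seq_len(config$n_heritable)]
    effects <- matrix(stats::rnorm(nc * config$n_heritable, 0, config$clone_sd),
                      nc, config$n_heritable, dimnames = list(clones, heritable))
    case <- cond_names[length(cond_names)]
    case_clones <- clones[clone_cond == case]
    n_high <- round(config$frac_high * length(case_clones))
    high <- if (n_high > 0) sample(case_clones, n_high) else character(0)
    if (length(high) && config$n_heritable > 0)
      effects[high, 1L] <- effects[high, 1L] + config$high_shift

    noise_sd <- ifelse(condition == case,
                       config$noise_sd * config$noise_ratio, config$noise_sd)
    scores <- matrix(stats::rnorm(n * nf, 0, noise_sd), n, nf,
                     dimnames = list(cells, feats))
    if (config$n_heritable > 0) {
      shift <- config$conditions[condition]
      scores[, heritable] <- scores[, heritable] +
        effects[clone, , drop = FALSE] + shift
    }
    structure(list(scores = scores, clone = clone, condition = condition,
                   truth = list(heritable = heritable, clone_effects = effects,
                                high_clones = high, clone_condition = clone_cond)),
              class = "sim_clonal_scores")
  })
}

#' Simulate lineage-barcode reads for a set of cells
#'
#' Emits one read record per sequencing read: a random prefix, the anchor
#' \code{TAGACAT}, then the cell's clone barcode, with independent per-base
#' substitutions at \code{error_rate}. Each cell carries
#' \code{umis_per_cell} UMIs and each cell-UMI-barcode triple is sequenced
#' \code{reads_per_triple} times. Decoy reads (no anchor) and poly-G UMIs
#' are injected at configurable rates to exercise the parser's rejection
#' branches.
#'
#' @param cell_clone Named character vector, cell barcode to clone id.
#' @param barcodes Named character vector of 48-bp clone barcodes (names are
#'   clone ids; every clone in \code{cell_clone} must be present).
#' @param reads_per_triple,umis_per_cell Read support structure.
#' @param error_rate Per-base substitution probability.
#' @param decoy_frac Probability that a read is replaced by an anchor-free
#'   random sequence.
#' @param polyg_frac Probability that a triple's UMI is all G.
#' @param prefix_len Length of the random prefix preceding the anchor.
#' @param template A [barcode_template()].
#' @param seed Integer seed.
#' @return A data.frame of class \code{"barcode_reads"} with columns
#'   \code{cell}, \code{umi}, \code{sequence} (one row per read) and
#'   attributes \code{truth} (cell_clone, barcodes) and \code{is_decoy}.
#' @export
simulate_barcode_reads <- function(cell_clone, barcodes,
                                   reads_per_triple = 10L, umis_per_cell = 3L,
                                   error_rate = 0, decoy_frac = 0,
                                   polyg_frac = 0, prefix_len = 10L,
                                   template = barcode_template(), seed = 1L) {
  missing_bc <- setdiff(unique(cell_clone), names(barcodes))
  if (length(missing_bc))
    stop("clones without a barcode: ", paste(missing_bc, collapse = ", "))
  with_seed(derive_seed(seed, 2L), {
    cells <- names(cell_clone)
    n_triple <- length(cells) * umis_per_cell
    tcell <- rep(cells, each = umis_per_cell)
    umi <- random_dna(n_triple, template$umi_length)
    while (any(allg <- grepl("^G+$", umi)))
      umi[allg] <- random_dna(sum(allg), template$umi_length)
    if (polyg_frac > 0) {
      pg <- stats::runif(n_triple) < polyg_frac
      umi[pg] <- strrep("G", template$umi_length)
    }
    bc <- barcodes[cell_clone[tcell]]
    idx <- rep(seq_len(n_triple), each = reads_per_triple)
    prefix <- random_dna(length(idx), prefix_len)
    seqs <- paste0(prefix, template$anchor, bc[idx])
    seqs <- mutate_sequences(seqs, error_rate)
    is_decoy <- rep(FALSE, length(idx))
    if (decoy_frac > 0) {
      is_decoy <- stats::runif(length(idx)) < decoy_frac
      if (any(is_decoy)) {
        dec <- random_dna(sum(is_decoy), prefix_len + 7L + template$width)
        # regenerate any decoy that contains the anchor within 1 mismatch
        repeat {
          hit <- find_anchor(dec, template$anchor, 1L) > 0L
          if (!any(hit)) break
          dec[hit] <- random_dna(sum(hit), prefix_len + 7L + template$width)
        }
        seqs[is_decoy] <- dec
      }
    }
    out <- data.frame(cell = tcell[idx], umi = umi[idx], sequence = seqs,
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(cell_clone = cell_clone, barcodes = barcodes)
    attr(out, "is_decoy") <- is_decoy
    class(out) <- c("barcode_reads", "data.frame")
    out
  })
}

#' Simulate a cell-by-peak count matrix with motif-family annotations
#'
#' Per-cell depths are log-normal; conditional on its depth a cell's counts
#' are multinomial over peak weights, so per-cell totals equal the drawn
#' depth exactly. A fraction of cells in the case (last) condition carries a
#' multiplicative fold-increase on the target family's peaks -- the
#' activated subpopulation the deviation scores should detect.
#'
#' @param n_cells,n_peaks,n_families,family_size Problem size. Families are
#'   disjoint-within, possibly overlapping across, random peak sets.
#' @param condition_frac Named fractions of cells per condition (last =
#'   case).
#' @param effect_fold Fold-increase on target-family peaks in affected
#'   cells.
#' @param frac_affected Fraction of case-condition cells affected.
#' @param target_family Index of the family carrying the planted effect.
#' @param depth_meanlog,depth_sdlog Log-normal depth parameters.
#' @param seed Integer seed.
#' @return A list of class \code{"sim_counts"}: \code{counts} (sparse cells
#'   x peaks), \code{annotations} (named list of peak indices),
#'   \code{condition}, \code{depth} and \code{truth} (affected cells,
#'   target family).
#' @export
simulate_counts_and_annotations <- function(n_cells = 1000L, n_peaks = 2000L,
                                            n_families = 5L, family_size = 100L,
                                            condition_frac = c(control = 0.5,
                                                               recovered = 0.5),
                                            effect_fold = 2, frac_affected = 0.1,
                                            target_family = 1L,
                                            depth_meanlog = log(5000),
                                            depth_sdlog = 0.3, seed = 1L) {
  stopifnot(abs(sum(condition_frac) - 1) < 1e-8, effect_fold > 0,
            frac_affected >= 0, frac_affected <= 1)
  with_seed(derive_seed(seed, 3L), {
    cells <- sprintf("cell_%05d", seq_len(n_cells))
    peaks <- sprintf("peak_%05d", seq_len(n_peaks))
    w <- stats::rgamma(n_peaks, shape = 2, rate = 2)
    w <- w / sum(w)
    fams <- stats::setNames(
      lapply(seq_len(n_families), function(i) sort(sample(n_peaks, family_size))),
      sprintf("family_%s", LETTERS[seq_len(n_families)]))
    cond <- rep(names(condition_frac),
                times = diff(round(cumsum(c(0, condition_frac)) * n_cells)))
    cond <- sample(cond)
    names(cond) <- cells
    case <- names(condition_frac)[length(condition_frac)]
    affected <- cells[cond == case & stats::runif(n_cells) < frac_affected]
    depth <- pmax(1L, round(stats::rlnorm(n_cells, depth_meanlog, depth_sdlog)))
    target <- fams[[target_family]]
    w_aff <- w
    w_aff[target] <- w_aff[target] * effect_fold
    w_aff <- w_aff / sum(w_aff)

    ii <- vector("list", n_cells); xx <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      p <- if (cells[i] %in% affected) w_aff else w
      cnt <- stats::rmultinom(1L, depth[i], p)[, 1L]
      nz <- which(cnt > 0L)
      ii[[i]] <- nz; xx[[i]] <- cnt[nz]
    }
    counts <- Matrix::sparseMatrix(
      i = rep.int(seq_len(n_cells), lengths(ii)),
      j = unlist(ii), x = unlist(xx),
      dims = c(n_cells, n_peaks), dimnames = list(cells, peaks))
    structure(list(counts = counts, annotations = fams, condition = cond,
                   depth = stats::setNames(depth, cells),
                   truth = list(affected_cells = affected,
                                target_family = names(fams)[target_family])),
              class = "sim_counts")
  })
}

#' Simulate per-condition footprint-score tables with planted memory gains
#'
#' Peaks are tiled in 10-bp bins. Motif sites for two TF families are
#' planted with a controlled co-occurrence odds ratio between their memory
#' memberships; at memory sites the case condition gains \code{delta} over
#' the control, and co-occurring sites within a peak sit
#' \code{pair_distance} bp apart (midpoint to midpoint).
#'
#' @param n_peaks Number of peaks.
#' @param bins_per_peak Number of 10-bp bins per peak.
#' @param families Two family names.
#' @param p_member Marginal probability that a peak carries a memory site of
#'   each family.
#' @param odds_ratio Planted co-occurrence odds ratio between the two
#'   families' memory memberships.
#' @param delta Planted footprint-score gain at memory sites (>= 0.2 makes
#'   them recoverable at the standard threshold; 0 plants nothing).
#' @param pair_distance Midpoint separation (bp) of co-occurring sites;
#'   rounded to the 10-bp grid.
#' @param p_nonmem Probability of an extra non-memory (no gain) motif site
#'   per peak per family.
#' @param conditions Names of the control and case conditions, in order.
#' @param noise Half-width of uniform case-vs-control jitter on
#'   non-memory bins (0 = noiseless).
#' @param seed Integer seed.
#' @return A list of class \code{"sim_footprints"}: \code{footprints}
#'   (data.frame peak, bin_start, condition, score), \code{sites}
#'   (data.frame family, peak, bin_start), and \code{truth} (per-family
#'   memory membership, planted memory sites, the realized 2x2 table).
#' @export
simulate_footprints <- function(n_peaks = 300L, bins_per_peak = 30L,
                                families = c("AP1", "FOX"),
                                p_member = c(0.3, 0.3), odds_ratio = 32,
                                delta = 0.3, pair_distance = 20L,
                                p_nonmem = 0.1,
                                conditions = c("control", "recovered"),
                                noise = 0, seed = 1L) {
  stopifnot(length(families) == 2L, length(conditions) == 2L,
            all(p_member > 0), all(p_member < 1))
  with_seed(derive_seed(seed, 4L), {
    pA <- p_member[1L]; pB <- p_member[2L]; psi <- odds_ratio
    p11 <- if (abs(psi - 1) < 1e-12) pA * pB else {
      s <- 1 + (pA + pB) * (psi - 1)
      (s - sqrt(s^2 - 4 * psi * (psi - 1) * pA * pB)) / (2 * (psi - 1))
    }
    probs <- c(both = p11, first = pA - p11, second = pB - p11,
               neither = 1 - pA - pB + p11)
    stopifnot(all(probs > -1e-12))
    cat4 <- sample(names(probs), n_peaks, replace = TRUE, prob = pmax(probs, 0))
    memA <- cat4 %in% c("both", "first")
    memB <- cat4 %in% c("both", "second")
    peaks <- sprintf("peak_%04d", seq_len(n_peaks))
    sep_bins <- max(1L, as.integer(round(pair_distance / 10)))
    interior <- seq_len(bins_per_peak - sep_bins - 1L)

    site_rows <- list(); mem_rows <- list()
    for (i in seq_len(n_peaks)) {
      rows <- NULL
      if (memA[i]) {
        a_bin <- sample(interior, 1L)
        rows <- rbind(rows, data.frame(family = families[1L], peak = peaks[i],
                                       bin = a_bin, memory = delta > 0))
        if (memB[i])
          rows <- rbind(rows, data.frame(family = families[2L], peak = peaks[i],
                                         bin = a_bin + sep_bins, memory = delta > 0))
      } else if (memB[i]) {
        rows <- rbind(rows, data.frame(family = families[2L], peak = peaks[i],
                                       bin = sample(interior, 1L), memory = delta > 0))
      }
      for (f in 1:2) if (stats::runif(1) < p_nonmem) {
        used <- if (is.null(rows)) integer(0) else rows$bin[rows$peak == peaks[i]]
        free <- setdiff(seq_len(bins_per_peak), used)
        if (length(free))
          rows <- rbind(rows, data.frame(family = families[f], peak = peaks[i],
                                         bin = sample(free, 1L), memory = FALSE))
      }
      if (!is.null(rows)) site_rows[[length(site_rows) + 1L]] <- rows
    }
    sites_all <- if (length(site_rows)) do.call(rbind, site_rows) else
      data.frame(family = character(0), peak = character(0),
                 bin = integer(0), memory = logical(0))
    sites_all$bin_start <- (sites_all$bin - 1L) * 10L

    grid <- expand.grid(bin_start = (seq_len(bins_per_peak) - 1L) * 10L,
                        peak = peaks, stringsAsFactors = FALSE)
    base <- stats::runif(nrow(grid), 0.05, 0.55)
    key <- paste(grid$peak, grid$bin_start)
    mem_key <- paste(sites_all$peak, sites_all$bin_start)[sites_all$memory]
    is_mem <- key %in% mem_key
    base[is_mem] <- stats::runif(sum(is_mem), 0.25, 0.5)
    case_score <- base + ifelse(is_mem, delta, 0)
    if (noise > 0) {
      jit <- stats::runif(nrow(grid), -noise, noise)
      case_score[!is_mem] <- pmin(1.5, pmax(0, case_score[!is_mem] + jit[!is_mem]))
    }
    fp <- rbind(
      data.frame(peak = grid$peak, bin_start = grid$bin_start,
                 condition = conditions[1L], score = base,
                 stringsAsFactors = FALSE),
      data.frame(peak = grid$peak, bin_start = grid$bin_start,
                 condition = conditions[2L], score = case_score,
                 stringsAsFactors = FALSE))
    membership <- cbind(memA, memB)
    colnames(membership) <- families
    rownames(membership) <- peaks
    if (delta <= 0) membership[] <- FALSE
    structure(list(
      footprints = fp,
      sites = sites_all[, c("family", "peak", "bin_start")],
      truth = list(membership = membership,
                   memory_sites = sites_all[sites_all$memory,
                                            c("family", "peak", "bin_start")],
                   table = table(factor(memA, c(TRUE, FALSE)),
                                 factor(memB, c(TRUE, FALSE))),
                   pair_distance = sep_bins * 10L)),
      class = "sim_footprints")
  })
}

#' Simulate a spatial section with contiguous marker-high tumor regions
#'
#' Generates a regular grid of bins. Disc-shaped tumor regions carry a
#' fold-increase of the marker gene; a subset of tumors (the planted
#' high-program tumors) additionally up-regulates a program gene set.
#' Per-bin counts are multinomial given a log-normal depth; a small
#' fraction of bins is given sub-threshold depth to exercise the read-depth
#' QC filter.
#'
#' @param n_x,n_y Grid dimensions (bin units).
#' @param n_genes Number of genes; gene 1 is the marker (named
#'   \code{marker}), the next \code{n_program_genes} form the program and
#'   the following \code{n_signature_genes} the tumor-identity signature.
#' @param n_tumors Number of planted tumors.
#' @param tumor_radius Tumor disc radius in bin units.
#' @param min_separation Minimum center-to-center distance between tumors
#'   (bin units); default keeps tumors well separated.
#' @param high_fraction Fraction of tumors planted as program-high.
#' @param marker_fold,program_fold,signature_fold Expression
#'   fold-increases. The signature genes are elevated in every tumor bin
#'   (adenomas are transcriptomically distinct well beyond one marker),
#'   the program genes only in high tumors.
#' @param marker Marker gene name.
#' @param n_program_genes Size of the program gene set.
#' @param depth_meanlog,depth_sdlog Log-normal depth parameters.
#' @param frac_low_depth Fraction of bins given depth below 300 reads.
#' @param seed Integer seed.
#' @return A list of class \code{"sim_spatial"}: \code{coords} (data.frame
#'   x, y), \code{counts} (sparse bins x genes), \code{program_genes}, and
#'   \code{truth} (per-bin tumor id, 0 = background; high tumor ids;
#'   centers).
#' @export
simulate_spatial_section <- function(n_x = 48L, n_y = 48L, n_genes = 120L,
                                     n_tumors = 2L, tumor_radius = 4,
                                     min_separation = max(12, 4 * tumor_radius),
                                     high_fraction = 0.5,
                                     marker_fold = 8, program_fold = 3,
                                     signature_fold = 4,
                                     marker = "Axin2", n_program_genes = 20L,
                                     n_signature_genes = 15L,
                                     depth_meanlog = log(800),
                                     depth_sdlog = 0.3,
                                     frac_low_depth = 0.05, seed = 1L) {
  with_seed(derive_seed(seed, 5L), {
    coords <- expand.grid(x = seq_len(n_x), y = seq_len(n_y))
    n_bins <- nrow(coords)
    genes <- c(marker, sprintf("prog_gene_%02d", seq_len(n_program_genes)),
               sprintf("sig_gene_%02d", seq_len(n_signature_genes)),
               sprintf("gene_%04d",
                       seq_len(n_genes - 1L - n_program_genes -
                                 n_signature_genes)))
    prog <- genes[2:(1L + n_program_genes)]
    sig <- genes[(2L + n_program_genes):(1L + n_program_genes +
                                           n_signature_genes)]
    # place tumor centers by rejection to enforce separation and margins
    margin <- tumor_radius + 1
    centers <- matrix(NA_real_, 0L, 2L)
    tries <- 0L
    while (nrow(centers) < n_tumors && tries < 20000L) {
      tries <- tries + 1L
      cand <- c(stats::runif(1, margin, n_x - margin),
                stats::runif(1, margin, n_y - margin))
      if (nrow(centers) == 0L ||
          min(sqrt(colSums((t(centers) - cand)^2))) >= min_separation)
        centers <- rbind(centers, cand)
    }
    if (nrow(centers) < n_tumors)
      stop("could not place tumors with the requested separation")
    tumor <- integer(n_bins)
    for (t in seq_len(n_tumors)) {
      d2 <- (coords$x - centers[t, 1L])^2 + (coords$y - centers[t, 2L])^2
      tumor[d2 <= tumor_radius^2 & tumor == 0L] <- t
    }
    n_high <- round(high_fraction * n_tumors)
    high <- if (n_high > 0) sort(sample(seq_len(n_tumors), n_high)) else integer(0)

    w <- stats::rgamma(n_genes, shape = 2, rate = 2)
    w <- w / sum(w)
    names(w) <- genes
    depth <- pmax(301L, round(stats::rlnorm(n_bins, depth_meanlog, depth_sdlog)))
    low <- stats::runif(n_bins) < frac_low_depth
    depth[low] <- round(stats::runif(sum(low), 50, 299))

    ii <- vector("list", n_bins); xx <- vector("list", n_bins)
    for (i in seq_len(n_bins)) {
      wi <- w
      if (tumor[i] > 0L) {
        wi[marker] <- wi[marker] * marker_fold
        wi[sig] <- wi[sig] * signature_fold
        if (tumor[i] %in% high) wi[prog] <- wi[prog] * program_fold
        wi <- wi / sum(wi)
      }
      cnt <- stats::rmultinom(1L, depth[i], wi)[, 1L]
      nz <- which(cnt > 0L)
      ii[[i]] <- nz; xx[[i]] <- cnt[nz]
    }
    bins <- sprintf("bin_%05d", seq_len(n_bins))
    counts <- Matrix::sparseMatrix(
      i = rep.int(seq_len(n_bins), lengths(ii)), j = unlist(ii), x = unlist(xx),
      dims = c(n_bins, n_genes), dimnames = list(bins, genes))
    rownames(coords) <- bins
    structure(list(coords = coords, counts = counts, program_genes = prog,
                   marker = marker,
                   truth = list(tumor = stats::setNames(tumor, bins),
                                high_tumors = high, centers = centers)),
              class = "sim_spatial")
  })
}
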