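#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The defaults describe a toy
#' genome (2 chromosomes x 100 kb, 20 coding genes, 40 TE copies) carrying
#' the statistical structure the analysis assumes: IP enrichment
#' concentrated near stop codons (60% of true peaks in the stop-codon
#' window) with planted RRACH motifs, methylation preferentially on ZGA
#' transcripts (probability 0.8 given ZGA vs 0.3 otherwise) and on LTR/MERVL
#' copies, ZGA genes activated 8-fold in the 2CLC condition, a three-state
#' single-cell transition in which m6A+ ZGA transcripts decline faster than
#' m6A- ones, and exponential decay courses with condition-dependent rates.
#'
#' @param seed integer master seed; every generator derives its stream from
#'   it deterministically.
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes number of coding genes (placed non-overlapping).
#' @param frac_zga,frac_pluripotent fractions of genes in the ZGA and
#'   pluripotency categories (the rest are "other").
#' @param n_te_copies named vector of TE copy counts per class
#'   (DNA/SINE/LINE/LTR).
#' @param bin_size coverage bin width in bp.
#' @param reads_per_library target library size per coverage track.
#' @param peak_ip_fold IP/input enrichment at true peaks (> 1).
#' @param p_m6a_given_zga_up,p_m6a_given_other methylation probabilities per
#'   gene category in the 2CLC condition (the "other" probability also
#'   applies to all genes in ESC).
#' @param p_m6a_given_ltr,p_m6a_given_te_other per-copy methylation
#'   probabilities for LTR vs non-LTR TE copies in 2CLC.
#' @param p_stop_codon probability that a true gene peak sits in the
#'   stop-codon window (remainder uniform over CDS/3'UTR).
#' @param peak_width true peak width in bp.
#' @param fc_zga_2clc fold activation of ZGA genes in 2CLC (pluripotency
#'   genes are down by the same fold).
#' @param frac_other_up fraction of "other" genes also activated in 2CLC,
#'   so the up-DEG set contains both ZGA and non-ZGA members as in the
#'   contingency analysis.
#' @param n_cells named vector of cell counts per state
#'   (2CLC/transient/pluripotent).
#' @param sc_time_span effective elapsed time (hours) spanned by the
#'   2CLC -> pluripotent latent trajectory, converting per-hour decay rates
#'   into per-transition decline.
#' @param decay_rate_m6a,decay_rate_non_m6a per-hour first-order decay rates
#'   of m6A+ and m6A- ZGA transcripts.
#' @param inhibitor_factor multiplier (< 1) applied to the decay rate of
#'   m6A+ genes under methyltransferase inhibition.
#' @param decay_noise multiplicative (log-normal sd) noise on decay courses.
#' @param spike_noise multiplicative noise on spike-in measurements.
#' @param noise_dispersion negative-binomial dispersion of coverage counts
#'   and log-normal sd of expression replicates.
#' @param tss_flank,stop_flank feature-derivation flanks (bp).
#' @return Object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2, chrom_length = 100000,
                       n_genes = 20, frac_zga = 0.3, frac_pluripotent = 0.3,
                       n_te_copies = c(DNA = 10, SINE = 10, LINE = 10,
                                       LTR = 10),
                       bin_size = 50, reads_per_library = 2e5,
                       peak_ip_fold = 8,
                       p_m6a_given_zga_up = 0.8, p_m6a_given_other = 0.3,
                       p_m6a_given_ltr = 0.8, p_m6a_given_te_other = 0.1,
                       p_stop_codon = 0.6, peak_width = 200,
                       fc_zga_2clc = 8, frac_other_up = 0.3,
                       n_cells = c("2CLC" = 40, transient = 40,
                                   pluripotent = 40),
                       sc_time_span = 6,
                       decay_rate_m6a = 0.5, decay_rate_non_m6a = 0.2,
                       inhibitor_factor = 0.5, decay_noise = 0.1,
                       spike_noise = 0.05, noise_dispersion = 0.1,
                       tss_flank = 100, stop_flank = 200) {
  cfg <- as.list(environment())
  probs <- c(frac_zga, frac_pluripotent, p_m6a_given_zga_up,
             p_m6a_given_other, p_m6a_given_ltr, p_m6a_given_te_other,
             p_stop_codon)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]",
                                       call. = FALSE)
  if (peak_ip_fold < 1) stop("peak_ip_fold must be >= 1 (1 = null, no enrichment)",
                             call. = FALSE)
  if (decay_rate_m6a < 0 || decay_rate_non_m6a < 0 || noise_dispersion < 0)
    stop("rates and dispersion must be non-negative", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

## expression of one TE family in one condition (arbitrary units feeding
## coverage and the family rows of the bulk matrix); MERVL is the dominant
## repeat transcript of the 2CLC condition
.te_expr <- function(family, condition) {
  base <- 20
  if (family == "MERVL" && condition == "2CLC") return(400)
  base
}

#' Simulate the toy genome annotation and its ground truth
#'
#' Places non-overlapping coding genes (2-4 exons each, valid CDS with
#' non-empty UTRs and an in-exon stop codon), drops TE copies into the
#' remaining intergenic space (MERVL as an LTR family with full-length
#' flags), assigns gene categories (ZGA / pluripotent / other), samples
#' per-condition m6A status from the category-conditional probabilities,
#' lays out the true m6A peaks (60% in stop-codon windows by default) and
#' writes a random genome sequence with RRACH motifs planted inside true
#' peak spans. Deterministic given \code{cfg$seed}.
#'
#' @param cfg a [sim_config()].
#' @return List of class \code{m6a_sim}: \code{cfg}, \code{genome},
#'   \code{genes}, \code{te}, \code{sequences}
#'   (\code{Biostrings::DNAStringSet}) and \code{truth} (gene table, TE
#'   table, true peak table keyed by condition).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(as.integer(cfg$seed), {
    chroms <- paste0("chr", seq_len(cfg$n_chroms))
    genome <- genome_table(chroms, rep(cfg$chrom_length, cfg$n_chroms))
    ## --- genes, placed sequentially with random gaps, round-robin chroms
    cursor <- stats::setNames(rep(1000, cfg$n_chroms), chroms)
    ng <- max(cfg$n_genes, 0)
    g_chrom <- character(ng); g_strand <- character(ng)
    g_es <- character(ng); g_ee <- character(ng)
    g_cs <- integer(ng); g_ce <- integer(ng)
    for (i in seq_len(ng)) {
      ch <- chroms[(i - 1) %% cfg$n_chroms + 1]
      n_ex <- sample(2:4, 1)
      exlen <- sample(150:400, n_ex, replace = TRUE)
      intlen <- if (n_ex > 1) sample(200:600, n_ex - 1, replace = TRUE)
                else integer(0)
      gap <- sample(500:1500, 1)
      start <- cursor[[ch]] + gap
      es <- start + c(0, cumsum(exlen[-n_ex] + intlen))
      ee <- es + exlen
      span_end <- ee[n_ex]
      if (span_end + cfg$tss_flank + cfg$stop_flank >= cfg$chrom_length)
        stop("capacity error: genome too small for requested gene count",
             call. = FALSE)
      g_chrom[i] <- ch
      g_strand[i] <- sample(c("+", "-"), 1)
      g_es[i] <- paste(es, collapse = ",")
      g_ee[i] <- paste(ee, collapse = ",")
      g_cs[i] <- es[1] + sample(50:100, 1)
      g_ce[i] <- ee[n_ex] - sample(50:120, 1)
      cursor[[ch]] <- span_end
    }
    genes <- data.frame(gene_id = sprintf("g%03d", seq_len(ng)),
                        chrom = g_chrom, strand = g_strand,
                        exon_starts = g_es, exon_ends = g_ee,
                        cds_start = g_cs, cds_end = g_ce,
                        biotype = rep("coding", ng),
                        stringsAsFactors = FALSE)
    if (nrow(genes)) validate_gene_models(genes)
    ## --- gene categories
    n <- nrow(genes)
    n_zga <- round(cfg$frac_zga * n)
    n_plu <- round(cfg$frac_pluripotent * n)
    category <- rep("other", n)
    if (n > 0) {
      idx <- sample.int(n)
      category[idx[seq_len(n_zga)]] <- "ZGA"
      if (n_plu > 0) category[idx[n_zga + seq_len(n_plu)]] <- "pluripotent"
    }
    ## --- TE copies in intergenic space (greedy placement into free gaps)
    spans <- gene_spans(genes)
    margin <- 300L
    if (nrow(spans)) {
      spans$start <- pmax(spans$start - margin, 0L)
      spans$end <- spans$end + margin
    }
    free <- .complement_intervals(spans, genome)
    telist <- list()
    fam_of <- list(DNA = c("hAT", "TcMar"), SINE = c("B1", "B2"),
                   LINE = c("L1", "L2"), LTR = c("MERVL", "ERVK"))
    for (cls in names(cfg$n_te_copies)) {
      k <- cfg$n_te_copies[[cls]]
      if (k == 0) next
      fams <- rep(fam_of[[cls]], length.out = k)
      for (j in seq_len(k)) {
        fam <- fams[j]
        len <- if (fam == "MERVL") sample(1500:2500, 1) else sample(300:800, 1)
        ok <- which(free$end - free$start >= len + 100)
        if (length(ok) == 0)
          stop("capacity error: no intergenic space left for TE copies",
               call. = FALSE)
        gi <- ok[sample.int(length(ok), 1)]
        g <- free[gi, ]
        st <- g$start + sample.int(g$end - g$start - len, 1)
        telist[[length(telist) + 1L]] <- data.frame(
          chrom = g$chrom, start = st, end = st + len,
          strand = sample(c("+", "-"), 1), te_class = cls, te_family = fam,
          full_length = fam == "MERVL" && len >= 1500,
          stringsAsFactors = FALSE)
        ## split the occupied gap
        free <- rbind(free[-gi, ],
                      data.frame(chrom = g$chrom, start = g$start, end = st,
                                 strand = ".", stringsAsFactors = FALSE),
                      data.frame(chrom = g$chrom, start = st + len,
                                 end = g$end, strand = ".",
                                 stringsAsFactors = FALSE))
        free <- free[free$end - free$start > 0, , drop = FALSE]
      }
    }
    te <- if (length(telist)) do.call(rbind, telist) else
      te_annotation(character(0), integer(0), integer(0), character(0),
                    character(0), character(0), logical(0))
    ## --- per-gene truth: expression and m6A status per condition
    base <- stats::rlnorm(n, meanlog = log(100), sdlog = 0.8)
    other_up <- category == "other" & stats::runif(n) < cfg$frac_other_up
    expr_2clc <- ifelse(category == "ZGA" | other_up, base * cfg$fc_zga_2clc,
                        base)
    expr_esc <- ifelse(category == "pluripotent", base * cfg$fc_zga_2clc,
                       base)
    p2 <- ifelse(category == "ZGA", cfg$p_m6a_given_zga_up,
                 cfg$p_m6a_given_other)
    m6a_2clc <- stats::runif(n) < p2
    m6a_esc <- stats::runif(n) < cfg$p_m6a_given_other
    gene_truth <- data.frame(gene_id = genes$gene_id, category = category,
                             other_up = other_up, base_expr = base,
                             expr_2CLC = expr_2clc, expr_ESC = expr_esc,
                             m6a_2CLC = m6a_2clc, m6a_ESC = m6a_esc,
                             stringsAsFactors = FALSE)
    ## --- per-TE truth
    pte <- ifelse(te$te_class == "LTR", cfg$p_m6a_given_ltr,
                  cfg$p_m6a_given_te_other)
    te_truth <- data.frame(te_row = seq_len(nrow(te)),
                           te_family = te$te_family,
                           m6a_2CLC = stats::runif(nrow(te)) < pte,
                           m6a_ESC = stats::runif(nrow(te)) <
                             cfg$p_m6a_given_te_other,
                           stringsAsFactors = FALSE)
    ## --- true peaks per condition
    stopw <- stop_codon_intervals(genes)
    spans0 <- gene_spans(genes)
    span_row <- match(genes$gene_id, spans0$gene_id)
    stop_row <- match(genes$gene_id, stopw$gene_id)
    peak_rows <- list()
    for (cond in c("2CLC", "ESC")) {
      st_gene <- if (cond == "2CLC") gene_truth$m6a_2CLC else gene_truth$m6a_ESC
      idx <- which(st_gene)
      if (length(idx) > 0) {
        w <- cfg$peak_width
        in_stop <- stats::runif(length(idx)) < cfg$p_stop_codon
        start <- integer(length(idx)); end <- integer(length(idx))
        for (j in seq_along(idx)) {
          i <- idx[j]
          if (in_stop[j]) {
            ## centred in the stop-codon window (peak stays inside the
            ## stop +/- stop_flank window for widths <= window size)
            ctr <- stopw$start[stop_row[i]] + 1L + sample(-100:100, 1)
            start[j] <- max(ctr - w %/% 2, 0)
            end[j] <- min(start[j] + w, cfg$chrom_length)
          } else {
            ## inside one exon, restricted to CDS/3'UTR exonic bases
            es <- .unpack(genes$exon_starts[i])
            ee <- .unpack(genes$exon_ends[i])
            lo <- pmax(es, genes$cds_start[i])
            elig <- which(ee - lo > 0)
            k <- elig[sample.int(length(elig), 1,
                                 prob = (ee - lo)[elig])]
            wk <- min(w, ee[k] - lo[k])
            off <- sample.int(ee[k] - lo[k] - wk + 1L, 1) - 1L
            start[j] <- lo[k] + off
            end[j] <- start[j] + wk
          }
        }
        peak_rows[[length(peak_rows) + 1L]] <- data.frame(
          chrom = genes$chrom[idx], start = as.integer(start),
          end = as.integer(end), strand = genes$strand[idx],
          condition = cond, origin = genes$gene_id[idx],
          stringsAsFactors = FALSE)
      }
      st_te <- if (cond == "2CLC") te_truth$m6a_2CLC else te_truth$m6a_ESC
      ti <- which(st_te)
      if (length(ti) > 0) {
        len <- te$end[ti] - te$start[ti]
        w <- pmin(cfg$peak_width, len - 20)
        start <- te$start[ti] + (len - w) %/% 2
        peak_rows[[length(peak_rows) + 1L]] <- data.frame(
          chrom = te$chrom[ti], start = as.integer(start),
          end = as.integer(start + w), strand = te$strand[ti],
          condition = cond, origin = sprintf("te%03d", ti),
          stringsAsFactors = FALSE)
      }
    }
    true_peaks <- if (length(peak_rows)) do.call(rbind, peak_rows) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 strand = character(0), condition = character(0),
                 origin = character(0), stringsAsFactors = FALSE)
    ## --- genome sequence with RRACH motifs planted inside true peaks
    seqs <- lapply(stats::setNames(chroms, chroms), function(ch) {
      sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE)
    })
    if (nrow(true_peaks) > 0) {
      up <- unique(true_peaks[, c("chrom", "start", "end")])
      for (ch in unique(up$chrom)) {
        d <- up[up$chrom == ch, , drop = FALSE]
        at <- unlist(lapply(seq_len(nrow(d)), function(i)
          seq(d$start[i] + 5, d$end[i] - 5, by = 40)))
        pos <- as.vector(outer(1:5, at, `+`))
        seqs[[ch]][pos] <- rep(c("G", "G", "A", "C", "T"), length(at))
      }
    }
    sequences <- Biostrings::DNAStringSet(
      vapply(seqs, paste, character(1), collapse = ""))
    structure(list(cfg = cfg, genome = genome, genes = genes, te = te,
                   sequences = sequences,
                   truth = list(gene = gene_truth, te = te_truth,
                                peaks = true_peaks)),
              class = "m6a_sim")
  })
}

#' Simulate a binned coverage track
#'
#' Per-bin counts follow a negative-binomial law whose mean is proportional
#' to the host transcript's expression in the requested condition (genes
#' over their exonic bases, TE copies over their spans, plus a small
#' background); bins inside true peaks of that condition have their mean
#' multiplied by \code{peak_ip_fold} in IP libraries only. Means are scaled
#' so the expected library size equals \code{reads_per_library}. Seeded from
#' \code{cfg$seed} plus a per-track offset (or an explicit \code{seed}).
#'
#' @param sim an \code{m6a_sim} from [simulate_annotation()].
#' @param condition \code{"2CLC"} or \code{"ESC"}.
#' @param library \code{"IP"} or \code{"input"}.
#' @param replicate replicate index (distinct seeds per replicate).
#' @param seed optional explicit seed.
#' @return A \code{coverage_track}.
#' @export
simulate_coverage <- function(sim, condition = "2CLC",
                              library = c("IP", "input"), replicate = 1,
                              seed = NULL) {
  library <- match.arg(library)
  cfg <- sim$cfg
  if (is.null(seed))
    seed <- cfg$seed + 101 * match(condition, c("2CLC", "ESC", "2C")) +
      17 * (library == "IP") + 1009 * replicate
  bs <- cfg$bin_size
  mu <- lapply(sim$genome, function(L) rep(0.05, ceiling(L / bs)))
  add_mass <- function(mu, ch, start, end, rate_per_bp) {
    v <- mu[[ch]]
    b0 <- floor(start / bs); b1 <- ceiling(end / bs) - 1
    idx <- (b0:b1) + 1L
    binstart <- (b0:b1) * bs
    ov <- pmin(binstart + bs, end) - pmax(binstart, start)
    v[idx] <- v[idx] + rate_per_bp * ov
    mu[[ch]] <- v
    mu
  }
  exf <- paste0("expr_", condition)
  ex <- gene_exons(sim$genes)
  for (i in seq_len(nrow(sim$genes))) {
    gid <- sim$genes$gene_id[i]
    e <- sim$truth$gene[sim$truth$gene$gene_id == gid, exf]
    d <- ex[ex$gene_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(d)))
      mu <- add_mass(mu, d$chrom[j], d$start[j], d$end[j], e / 1000)
  }
  for (i in seq_len(nrow(sim$te))) {
    e <- .te_expr(sim$te$te_family[i], condition)
    mu <- add_mass(mu, sim$te$chrom[i], sim$te$start[i], sim$te$end[i],
                   e / 1000)
  }
  if (library == "IP") {
    pk <- sim$truth$peaks
    pk <- pk[pk$condition == condition, , drop = FALSE]
    for (i in seq_len(nrow(pk))) {
      ch <- pk$chrom[i]
      b0 <- floor(pk$start[i] / bs); b1 <- ceiling(pk$end[i] / bs) - 1
      idx <- (b0:b1) + 1L
      binstart <- (b0:b1) * bs
      frac <- (pmin(binstart + bs, pk$end[i]) -
                 pmax(binstart, pk$start[i])) / bs
      mu[[ch]][idx] <- mu[[ch]][idx] * (1 + (cfg$peak_ip_fold - 1) * frac)
    }
  }
  total <- sum(vapply(mu, sum, numeric(1)))
  mu <- lapply(mu, function(v) v / total * cfg$reads_per_library)
  counts <- withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    lapply(mu, function(v) {
      if (cfg$noise_dispersion < 1e-8) stats::rpois(length(v), v)
      else stats::rnbinom(length(v), mu = v, size = 1 / cfg$noise_dispersion)
    })
  })
  coverage_track(counts, bs, label = library, condition = condition)
}

#' Simulate the bulk expression matrix
#'
#' Genes x samples (3 replicates per condition by default) Poisson counts
#' around condition means with log-normal replicate noise, plus one row per
#' TE family (named \code{TE:<family>}); MERVL is the most abundant repeat
#' row in the 2CLC condition.
#'
#' @param sim an \code{m6a_sim}.
#' @param n_reps replicates per condition (default 3).
#' @param conditions conditions to emit (default ESC and 2CLC).
#' @param seed optional explicit seed.
#' @return List with \code{counts} (matrix) and \code{conditions} (per
#'   column).
#' @export
simulate_expression <- function(sim, n_reps = 3,
                                conditions = c("ESC", "2CLC"), seed = NULL) {
  cfg <- sim$cfg
  if (is.null(seed)) seed <- cfg$seed + 33013
  fams <- unique(sim$te$te_family)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    cols <- list(); cond_out <- character(0)
    for (cond in conditions) {
      gmean <- sim$truth$gene[[paste0("expr_", cond)]]
      tmean <- vapply(fams, .te_expr, numeric(1), condition = cond)
      mu <- c(gmean, tmean)
      for (r in seq_len(n_reps)) {
        lam <- mu * exp(stats::rnorm(length(mu), 0, cfg$noise_dispersion))
        cols[[length(cols) + 1L]] <- stats::rpois(length(lam), lam)
        cond_out <- c(cond_out, cond)
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- c(sim$truth$gene$gene_id,
                          if (length(fams)) paste0("TE:", fams))
    colnames(counts) <- paste0(cond_out, "_", stats::ave(seq_along(cond_out),
                                                         cond_out,
                                                         FUN = seq_along))
    list(counts = counts, conditions = cond_out)
  })
}

#' Simulate single-cell counts along the 2CLC -> pluripotent transition
#'
#' Cells occupy a latent position u (2CLC 0, transient 0.5, pluripotent 1).
#' Designated marker genes follow the state-defining pattern (2CLC markers
#' high for u < 1, pluripotency markers high for u > 0, transient cells
#' expressing both sets); non-marker ZGA genes decline as
#' \code{exp(-k u T)} with k the gene's methylation-dependent decay rate and
#' T = \code{sc_time_span}; pluripotency-category genes rise with u; other
#' genes stay flat. Counts are Poisson around per-cell expected expression
#' with log-normal depth factors.
#'
#' @param sim an \code{m6a_sim}.
#' @param n_markers markers designated per state identity (default 5, capped
#'   by availability).
#' @param seed optional explicit seed.
#' @return List: \code{counts} (genes x cells), \code{true_states},
#'   \code{markers_2clc}, \code{markers_plurip}, \code{zga_m6a_pos},
#'   \code{zga_m6a_neg} (non-marker ZGA gene sets by 2CLC m6A status).
#' @export
simulate_single_cell <- function(sim, n_markers = 5, seed = NULL) {
  cfg <- sim$cfg
  if (is.null(seed)) seed <- cfg$seed + 70001
  gt <- sim$truth$gene
  zga <- gt$gene_id[gt$category == "ZGA"]
  plu <- gt$gene_id[gt$category == "pluripotent"]
  if (length(zga) < 2 || length(plu) < 1)
    stop("simulation needs at least 2 ZGA and 1 pluripotency genes",
         call. = FALSE)
  ord <- order(-gt$base_expr[match(zga, gt$gene_id)])
  markers_2clc <- zga[ord][seq_len(min(n_markers, max(length(zga) - 2, 1)))]
  markers_plurip <- plu[order(-gt$base_expr[match(plu, gt$gene_id)])][
    seq_len(min(n_markers, length(plu)))]
  rest_zga <- setdiff(zga, markers_2clc)
  m6a <- stats::setNames(gt$m6a_2CLC, gt$gene_id)
  zga_pos <- rest_zga[m6a[rest_zga]]
  zga_neg <- rest_zga[!m6a[rest_zga]]
  states <- rep(names(cfg$n_cells), cfg$n_cells)
  u <- c("2CLC" = 0, transient = 0.5, pluripotent = 1)[states]
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    genes <- gt$gene_id
    base_sc <- 20
    mean_mat <- matrix(0, nrow = length(genes), ncol = length(states),
                       dimnames = list(genes, NULL))
    for (g in genes) {
      cat_g <- gt$category[gt$gene_id == g]
      if (g %in% markers_2clc) {
        m <- base_sc * ifelse(u < 1, 1, 0.02)          # high in 2CLC+transient
      } else if (g %in% markers_plurip) {
        m <- base_sc * ifelse(u > 0, 1, 0.02)          # high in transient+plurip
      } else if (cat_g == "ZGA") {
        k <- if (m6a[g]) cfg$decay_rate_m6a else cfg$decay_rate_non_m6a
        m <- base_sc * exp(-k * u * cfg$sc_time_span)
      } else if (cat_g == "pluripotent") {
        m <- base_sc * (0.05 + 0.95 * u)
      } else {
        m <- rep(base_sc / 4, length(u))
      }
      mean_mat[g, ] <- m
    }
    depth <- exp(stats::rnorm(length(states), 0, 0.2))
    lam <- sweep(mean_mat, 2, depth, "*")
    counts <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam),
                     dimnames = list(genes,
                                     paste0("cell", seq_along(states))))
    list(counts = counts, true_states = unname(states),
         markers_2clc = markers_2clc, markers_plurip = markers_plurip,
         zga_m6a_pos = zga_pos, zga_m6a_neg = zga_neg)
  })
}

#' Simulate spike-in measurements
#'
#' GLuc (methylated) IP/input ratio centred on \code{true_enrichment}, CLuc
#' (unmethylated) centred on 1, with multiplicative log-normal noise.
#'
#' @param cfg a [sim_config()].
#' @param true_enrichment target GLuc/CLuc double ratio (default 10).
#' @param seed optional explicit seed.
#' @return List with gluc_ip, gluc_input, cluc_ip, cluc_input counts.
#' @export
simulate_spike_in <- function(cfg, true_enrichment = 10, seed = NULL) {
  if (is.null(seed)) seed <- cfg$seed + 90101
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    noise <- function() exp(stats::rnorm(1, 0, cfg$spike_noise))
    base <- 1000
    list(gluc_ip = base * true_enrichment * noise(),
         gluc_input = base * noise(),
         cluc_ip = base * noise(),
         cluc_input = base * noise())
  })
}

#' Simulate actinomycin-D decay courses
#'
#' ZGA transcripts decay as \code{exp(-k t)} with k set by their 2CLC m6A
#' status (\code{decay_rate_m6a} vs \code{decay_rate_non_m6a}); in the
#' inhibitor condition the rate of m6A+ genes is multiplied by
#' \code{inhibitor_factor} while m6A- genes are unchanged. Values carry
#' multiplicative log-normal noise at t > 0 and are 1 at t = 0.
#'
#' @param sim an \code{m6a_sim}.
#' @param timepoints hours (must include 0).
#' @param conditions subset of \code{c("ctrl", "inhibitor")}.
#' @param seed optional explicit seed.
#' @return List with \code{courses} (gene, condition, time_h, rel_expr) and
#'   the m6A+ / m6A- gene sets.
#' @export
simulate_decay <- function(sim, timepoints = c(0, 1, 2, 4, 8),
                           conditions = c("ctrl", "inhibitor"),
                           seed = NULL) {
  cfg <- sim$cfg
  if (is.null(seed)) seed <- cfg$seed + 55501
  stopifnot(0 %in% timepoints)
  gt <- sim$truth$gene
  zga <- gt[gt$category == "ZGA", , drop = FALSE]
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    rows <- list()
    for (i in seq_len(nrow(zga))) {
      k0 <- if (zga$m6a_2CLC[i]) cfg$decay_rate_m6a else cfg$decay_rate_non_m6a
      for (cond in conditions) {
        k <- if (cond == "inhibitor" && zga$m6a_2CLC[i])
          k0 * cfg$inhibitor_factor else k0
        v <- exp(-k * timepoints) *
          ifelse(timepoints == 0, 1,
                 exp(stats::rnorm(length(timepoints), 0, cfg$decay_noise)))
        rows[[length(rows) + 1L]] <- data.frame(
          gene = zga$gene_id[i], condition = cond, time_h = timepoints,
          rel_expr = v, stringsAsFactors = FALSE)
      }
    }
    list(courses = do.call(rbind, rows),
         m6a_pos = zga$gene_id[zga$m6a_2CLC],
         m6a_neg = zga$gene_id[!zga$m6a_2CLC])
  })
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the formats the pipeline reads: genome table TSV, gene-model TSV,
#' TE annotation TSV, true-peak BEDs per condition, genome FASTA, and the
#' ground-truth gene table.
#'
#' @param sim an \code{m6a_sim}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_table(sim$genome, file.path(dir, "genome.tsv"))
  write_gene_models(sim$genes, file.path(dir, "genes.tsv"))
  write_te_annotation(sim$te, file.path(dir, "te.tsv"))
  for (cond in unique(sim$truth$peaks$condition)) {
    pk <- sim$truth$peaks[sim$truth$peaks$condition == cond, , drop = FALSE]
    write_bed(pk, file.path(dir, paste0("true_peaks_", cond, ".bed")))
  }
  Biostrings::writeXStringSet(sim$sequences, file.path(dir, "genome.fa"))
  utils::write.table(sim$truth$gene, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
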