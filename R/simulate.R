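# Seeded synthetic-data generator. It emulates the generative structure
# the analyses assume — promoter-proximal RNAPII pausing on top of a flat
# gene-body signal with Poisson count noise, promoter GC-skew classes,
# copy-number segments embedded in a probe log2-ratio track with a
# controllable fraction planted inside feature regions, and qPCR Ct
# values that are Gaussian around -log2(abundance) — so every pipeline
# stage can be exercised, with known ground truth, without any external
# data. The default scenario (2 chromosomes x 5 Mb, 300 genes, 50 CNCs)
# is desk-scale: all simulations run in seconds.

#' Default configuration for the synthetic-data generator
#'
#' @param seed master integer seed.
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param n_genes number of genes, split across chromosomes in
#'   proportion to length.
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene-length
#'   parameters (bp); lengths are clamped to `[1000, 2e5]`.
#' @param frac_expressed fraction of genes carrying RNAPII signal.
#' @param lambda expected gene-body ChIP signal per bp for expressed
#'   genes.
#' @param lambda_input uniform input-track signal per bp.
#' @param lambda_bg ChIP background signal per bp outside genes.
#' @param pausing_wt,pausing_ko promoter signal multiplier (pausing
#'   factor) per condition; the promoter window carries
#'   `lambda * pausing`.
#' @param bin_width coverage bin width in bp.
#' @param skew_high,skew_low target promoter GC skew of the two skew
#'   classes.
#' @param frac_high_skew fraction of genes assigned to the high-skew
#'   class.
#' @param promoter_gc GC fraction of synthesized promoter windows.
#' @param n_cnc,cnc_length_bp number and length of simulated copy-number
#'   changes.
#' @param n_features,feature_length_bp number and length of feature
#'   (fragile-site-like) intervals.
#' @param planted_frac fraction of CNCs placed entirely inside features.
#' @param probe_spacing_bp,probe_noise_sd array-probe spacing and
#'   log2-ratio noise standard deviation.
#' @param cnc_amplitude absolute log2-ratio of embedded CNC segments.
#' @param qpcr_base_ct,qpcr_noise_sd,qpcr_replicates,qpcr_input_fraction
#'   qPCR simulation parameters (cycles at unit abundance, Gaussian Ct
#'   noise sd in cycles, technical replicates, input fraction).
#' @return a named list of parameters.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chrS1 = 5e6, chrS2 = 5e6),
                       n_genes = 300,
                       gene_length_meanlog = log(8000),
                       gene_length_sdlog = 0.6,
                       frac_expressed = 0.7,
                       lambda = 0.5,
                       lambda_input = 0.2,
                       lambda_bg = 0.02,
                       pausing_wt = 2,
                       pausing_ko = 4,
                       bin_width = 10,
                       skew_high = 0.4,
                       skew_low = -0.2,
                       frac_high_skew = 0.5,
                       promoter_gc = 0.5,
                       n_cnc = 50,
                       cnc_length_bp = 2000,
                       n_features = 25,
                       feature_length_bp = 20000,
                       planted_frac = 0.5,
                       probe_spacing_bp = 200,
                       probe_noise_sd = 0.1,
                       cnc_amplitude = 1.0,
                       qpcr_base_ct = 20,
                       qpcr_noise_sd = 0.1,
                       qpcr_replicates = 3,
                       qpcr_input_fraction = 0.01) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 0, cfg$frac_expressed >= 0, cfg$frac_expressed <= 1,
            cfg$pausing_wt >= 1, cfg$pausing_ko >= 1,
            cfg$planted_frac >= 0, cfg$planted_frac <= 1,
            cfg$lambda >= 0, cfg$lambda_input >= 0, cfg$lambda_bg >= 0,
            cfg$qpcr_noise_sd >= 0, all(cfg$chrom_lengths > 0))
  cfg
}

# Sense-strand promoter sequence with an (almost) exact target skew:
# base counts are fixed deterministically, only their arrangement is
# random, so the realized skew is within rounding of the target.
.skewed_window <- function(len, skew, gc_frac) {
  gc <- round(gc_frac * len)
  nG <- round(gc * (1 + skew) / 2)
  nC <- gc - nG
  at <- len - gc
  nA <- at %/% 2L
  nT <- at - nA
  paste(sample(rep(c("G", "C", "A", "T"), c(nG, nC, nA, nT))), collapse = "")
}

#' Simulate a genome sequence and a non-overlapping gene annotation
#'
#' Chromosome sequences are uniform-random ACGT; each gene's
#' promoter-proximal window (-30 to +300 bp of the TSS, sense strand) is
#' then rewritten with a fixed base composition whose GC skew matches the
#' gene's assigned class (`skew_high` or `skew_low`) to within rounding.
#' Genes are placed without overlap, on both strands, with at least
#' 400 bp between neighbors and a 2.5 kb margin at chromosome ends so
#' promoter windows and metagene flanks stay in bounds. Deterministic
#' given `config$seed`.
#'
#' @param config a [sim_config()] list.
#' @return a list: `genome_seq` (`DNAStringSet`), `genes` (gene-model
#'   data.frame with `expressed`, `skew_class`, `target_skew` ground
#'   truth), `genome` (`Seqinfo`).
#' @export
simulate_genome_genes <- function(config = sim_config()) {
  set.seed(config$seed)
  lens <- as.integer(config$chrom_lengths)
  names(lens) <- names(config$chrom_lengths)
  margin <- 2500L
  min_gap <- 400L

  seqs <- lapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  })

  n_per <- if (config$n_genes == 0L) integer(length(lens)) else
    as.vector(table(factor(sample(names(lens), config$n_genes, replace = TRUE,
                                  prob = lens / sum(lens)),
                           levels = names(lens))))
  genes <- list()
  gid <- 0L
  for (ci in seq_along(lens)) {
    n_c <- n_per[ci]
    if (n_c == 0L) next
    L <- pmin(pmax(round(rlnorm(n_c, config$gene_length_meanlog,
                                config$gene_length_sdlog)), 1000L), 2e5L)
    avail <- lens[ci] - 2L * margin
    free <- avail - sum(L) - min_gap * (n_c + 1L)
    if (free < 0) {
      stop("genes cannot be placed without overlap on ", names(lens)[ci],
           "; use fewer or shorter genes")
    }
    g <- runif(n_c + 1L)
    gaps <- min_gap + floor(g / sum(g) * free)
    starts <- margin + cumsum(gaps)[seq_len(n_c)] +
      c(0L, cumsum(L)[-n_c])
    ends <- starts + L - 1L
    strand <- sample(c("+", "-"), n_c, replace = TRUE)
    genes[[ci]] <- data.frame(
      gene_id = sprintf("gene%04d", gid + seq_len(n_c)),
      chrom = names(lens)[ci],
      strand = strand,
      tss = ifelse(strand == "+", starts, ends),
      tes = ifelse(strand == "+", ends, starts))
    gid <- gid + n_c
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(), chrom = character(),
               strand = character(), tss = integer(), tes = integer())
  rownames(genes) <- NULL

  genome_seq <- DNAStringSet(unlist(seqs))
  names(genome_seq) <- names(lens)

  if (nrow(genes)) {
    genes$expressed <- runif(nrow(genes)) < config$frac_expressed
    genes$skew_class <- ifelse(runif(nrow(genes)) < config$frac_high_skew,
                               "high", "low")
    genes$target_skew <- ifelse(genes$skew_class == "high",
                                config$skew_high, config$skew_low)
    w <- .gene_windows(genes)
    inserts <- vapply(seq_len(nrow(genes)), function(i) {
      s <- .skewed_window(w$pw_end[i] - w$pw_start[i] + 1L,
                          genes$target_skew[i], config$promoter_gc)
      if (genes$strand[i] == "-") {
        s <- as.character(reverseComplement(DNAString(s)))
      }
      s
    }, character(1))
    # promoter windows never overlap (>= 400 bp between genes), so one
    # replaceAt per chromosome rewrites them all
    for (chr in unique(genes$chrom)) {
      i <- which(genes$chrom == chr)
      genome_seq[[chr]] <- Biostrings::replaceAt(
        genome_seq[[chr]], IRanges(w$pw_start[i], w$pw_end[i]),
        DNAStringSet(inserts[i]))
    }
  }
  list(genome_seq = genome_seq,
       genes = validate_genes(genes),
       genome = Seqinfo(seqnames = names(lens), seqlengths = unname(lens)))
}

# Poisson-binned coverage track from a per-base rate RleList.
.poisson_track <- function(rate, genome, bin_width) {
  lens <- seqlengths(genome)
  out <- lapply(names(lens), function(chr) {
    v <- as.numeric(rate[[chr]])
    L <- length(v)
    nb <- L %/% bin_width
    rem <- L - nb * bin_width
    mu <- colMeans(matrix(v[seq_len(nb * bin_width)], nrow = bin_width))
    sig <- rpois(nb, mu * bin_width) / bin_width
    widths <- rep(bin_width, nb)
    if (rem > 0L) {
      mu_r <- mean(v[(nb * bin_width + 1L):L])
      sig <- c(sig, rpois(1L, mu_r * rem) / rem)
      widths <- c(widths, rem)
    }
    Rle(sig, widths)
  })
  names(out) <- names(lens)
  IRanges::RleList(out, compress = FALSE)
}

#' Simulate a ChIP or input coverage track
#'
#' ChIP tracks carry `lambda * pausing` expected signal per bp over the
#' promoter-proximal window and `lambda` over the gene body of every
#' expressed gene, plus `lambda_bg` everywhere; input tracks are a
#' uniform `lambda_input`. Counts are Poisson per `bin_width`-bp bin and
#' reported as signal per bp, so for an expressed gene the expected
#' traveling ratio is approximately the pausing factor.
#'
#' @param genes gene-model data.frame; an `expressed` logical column
#'   restricts signal to expressed genes (all genes otherwise).
#' @param genome a `Seqinfo`.
#' @param track `"chip"` or `"input"`.
#' @param pausing scalar pausing factor, or a per-gene vector named by
#'   `gene_id` (>= 1).
#' @param config a [sim_config()] list supplying the rate parameters.
#' @param seed integer seed for this track (defaults to `config$seed`).
#' @return an `RleList` coverage track.
#' @export
simulate_coverage <- function(genes, genome, track = c("chip", "input"),
                              pausing = 2, config = sim_config(),
                              seed = config$seed) {
  track <- match.arg(track)
  if (any(pausing < 1)) stop("pausing factors must be >= 1")
  set.seed(seed)
  if (track == "input") {
    base <- config$lambda_input
    rate <- IRanges::RleList(lapply(seqlengths(genome), function(L) {
      Rle(base, L)
    }), compress = FALSE)
    return(.poisson_track(rate, genome, config$bin_width))
  }
  expressed <- if (!is.null(genes$expressed)) genes$expressed else
    rep(TRUE, nrow(genes))
  eg <- genes[expressed, , drop = FALSE]
  pf <- if (length(pausing) == 1L) rep(pausing, nrow(eg)) else {
    if (is.null(names(pausing))) stop("per-gene pausing must be named")
    pausing[eg$gene_id]
  }
  if (anyNA(pf)) stop("missing pausing factor for some expressed genes")
  w <- .gene_windows(eg)
  body_ok <- w$bd_end >= w$bd_start
  prom <- GRanges(w$chrom, IRanges(w$pw_start, w$pw_end), seqinfo = genome)
  body <- GRanges(w$chrom[body_ok],
                  IRanges(w$bd_start[body_ok], w$bd_end[body_ok]),
                  seqinfo = genome)
  rate <- coverage(prom, weight = config$lambda * pf) +
    coverage(body, weight = rep(config$lambda, sum(body_ok))) +
    config$lambda_bg
  .poisson_track(rate, genome, config$bin_width)
}

#' Simulate CNC and feature region sets with a planted overlap fraction
#'
#' Places `n_features` feature intervals uniformly (then merges them),
#' then places `n_cnc` copy-number-change intervals: a fraction
#' `planted_frac` entirely inside features (uniformly among fitting
#' positions), the rest uniformly on the genome. Classes alternate
#' gain/loss. Also emits a probe log2-ratio table carrying each CNC as a
#' segment of `+/- cnc_amplitude` on top of Gaussian noise.
#'
#' @param genome a `Seqinfo`.
#' @param config a [sim_config()] list.
#' @param seed integer seed (defaults to `config$seed`).
#' @param probe_noise_sd noise sd for the emitted probe table (defaults
#'   to `config$probe_noise_sd`; use 0 for a noiseless table).
#' @return a list: `cnc` (`GRanges` with `cnc_class`), `features`
#'   (merged `GRanges`), `probes` (data.frame), `planted` (logical, per
#'   CNC).
#' @export
simulate_cnc_features <- function(genome, config = sim_config(),
                                  seed = config$seed,
                                  probe_noise_sd = config$probe_noise_sd) {
  set.seed(seed)
  lens <- seqlengths(genome)
  pick_chrom <- function(n) sample(names(lens), n, replace = TRUE,
                                   prob = lens / sum(lens))
  uniform_place <- function(n, L) {
    chr <- pick_chrom(n)
    starts <- floor(runif(n) * (lens[chr] - L + 1)) + 1
    GRanges(chr, IRanges(as.integer(starts), width = L), seqinfo = genome)
  }
  features <- reduce(uniform_place(config$n_features,
                                   config$feature_length_bp),
                     ignore.strand = TRUE)
  n_plant <- round(config$planted_frac * config$n_cnc)
  host <- features[width(features) >= config$cnc_length_bp]
  if (n_plant > 0 && length(host) == 0L) {
    stop("features too small to host planted CNC intervals")
  }
  place_planted <- function(n) {
    slots <- width(host) - config$cnc_length_bp + 1
    idx <- sample(length(host), n, replace = TRUE, prob = slots / sum(slots))
    starts <- start(host)[idx] + floor(runif(n) * slots[idx])
    GRanges(seqnames(host)[idx],
            IRanges(as.integer(starts), width = config$cnc_length_bp),
            seqinfo = genome)
  }
  n_free <- config$n_cnc - n_plant
  cnc <- c(if (n_plant > 0) place_planted(n_plant) else GRanges(seqinfo = genome),
           if (n_free > 0) uniform_place(n_free, config$cnc_length_bp) else
             GRanges(seqinfo = genome))
  planted <- c(rep(TRUE, n_plant), rep(FALSE, n_free))
  # CNC calls on a real array are disjoint segments; redraw any interval
  # closer than two probe spacings to an earlier one so planted segments
  # stay individually recoverable from the probe track
  min_sep <- 2L * config$probe_spacing_bp
  for (round in seq_len(200L)) {
    pad <- GRanges(seqnames(cnc),
                   IRanges(pmax(start(cnc) - min_sep, 1L),
                           end(cnc) + min_sep))
    hits <- findOverlaps(pad, cnc, ignore.strand = TRUE)
    redo <- unique(subjectHits(hits)[queryHits(hits) < subjectHits(hits)])
    if (!length(redo)) break
    if (round == 200L) stop("could not place non-overlapping CNC intervals; ",
                            "reduce n_cnc or cnc_length_bp")
    for (j in redo) {
      cnc[j] <- if (planted[j]) place_planted(1L) else
        uniform_place(1L, config$cnc_length_bp)
    }
  }
  mcols(cnc)$cnc_class <- rep_len(c("gain", "loss"), length(cnc))
  probes <- simulate_probe_table(cnc, genome,
                                 spacing = config$probe_spacing_bp,
                                 noise_sd = probe_noise_sd,
                                 amplitude = config$cnc_amplitude)
  list(cnc = cnc, features = features, probes = probes, planted = planted)
}

#' Probe log2-ratio table with embedded CNC segments
#'
#' Probes are evenly spaced along every chromosome; their log2 ratio is
#' Gaussian noise plus `+amplitude` inside gain intervals and
#' `-amplitude` inside losses.
#'
#' @param cnc `GRanges` with a `cnc_class` column (may be empty).
#' @param genome a `Seqinfo`.
#' @param spacing probe spacing in bp.
#' @param noise_sd Gaussian log2-ratio noise (0 for noiseless).
#' @param amplitude absolute segment log2 ratio.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return a probe data.frame (`chrom`, `pos`, `log2_ratio`).
#' @export
simulate_probe_table <- function(cnc, genome, spacing = 200, noise_sd = 0.1,
                                 amplitude = 1.0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- seqlengths(genome)
  probes <- do.call(rbind, lapply(names(lens), function(chr) {
    pos <- seq(spacing, lens[[chr]], by = spacing)
    data.frame(chrom = chr, pos = as.integer(pos),
               log2_ratio = rnorm(length(pos), 0, noise_sd))
  }))
  if (length(cnc)) {
    pgr <- GRanges(probes$chrom, IRanges(probes$pos, width = 1L))
    hits <- findOverlaps(pgr, cnc, ignore.strand = TRUE)
    shift <- ifelse(mcols(cnc)$cnc_class[subjectHits(hits)] == "gain",
                    amplitude, -amplitude)
    probes$log2_ratio[queryHits(hits)] <-
      probes$log2_ratio[queryHits(hits)] + shift
  }
  probes
}

#' Simulate a qPCR Ct table around known true abundances
#'
#' For each row of `truth` (columns `sample`, `region`,
#' `percent_input_true` — the true immunoprecipitated percentage of
#' input material), Ct values are drawn as
#' `base_ct - log2(abundance) + N(0, sd)` for the specific antibody, an
#' IgG control at `igg_percent`, and the input aliquot at
#' `input_fraction` of the total, in `replicates` technical replicates.
#' [summarize_qpcr()] on the emitted table recovers the true
#' percentages up to Ct noise.
#'
#' @param truth data.frame `sample`, `region`, `percent_input_true`.
#' @param config a [sim_config()] list (noise sd, replicates, base Ct,
#'   input fraction).
#' @param igg_percent true IgG percent input (default 0.2).
#' @param seed integer seed (defaults to `config$seed`).
#' @return a Ct data.frame as accepted by [validate_ct_table()].
#' @export
simulate_qpcr <- function(truth, config = sim_config(), igg_percent = 0.2,
                          seed = config$seed) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    ab_abundance <- c(specific = truth$percent_input_true[i] / 100,
                      IgG = igg_percent / 100,
                      input = config$qpcr_input_fraction)
    do.call(rbind, lapply(names(ab_abundance), function(ab) {
      data.frame(sample = truth$sample[i], region = truth$region[i],
                 antibody = ab, replicate = seq_len(config$qpcr_replicates),
                 ct = config$qpcr_base_ct - log2(ab_abundance[[ab]]) +
                   rnorm(config$qpcr_replicates, 0, config$qpcr_noise_sd),
                 input_fraction = config$qpcr_input_fraction)
    }))
  })
  validate_ct_table(do.call(rbind, rows))
}
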