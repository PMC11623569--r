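#' Simulation configuration
#'
#' Defines the synthetic study conditions: a random reference genome, a
#' non-overlapping gene layout on both strands, planted Psi sites at uridine
#' positions, and paired bisulfite-treated/untreated pileups generated
#' directly in count space (the method consumes pileups, so simulating reads
#' would only add aligner dependence). Deletion counts are binomial:
#' untreated positions delete at the background rate, treated planted sites
#' at background + stoichiometry, and (microbiome mode) strain-heterogeneity
#' positions add a treatment-independent deletion rate to both halves.
#'
#' @param seed Integer RNG seed governing every random choice.
#' @param genome_length Reference length in nt (default 1e5, >= 1000).
#' @param gc_content GC fraction in (0, 1), default 0.5 (enteric-bacteria
#'   like).
#' @param n_genes Number of non-overlapping genes tiled on both strands.
#' @param n_psi_sites Number of planted Psi sites.
#' @param stoichiometry Either a fixed value or `c(min, max)` for a uniform
#'   draw per site; default `c(0.05, 0.6)`, spanning the calling floor (a 5%
#'   deletion fraction) up to the strong sites seen in deep libraries.
#' @param mean_depth Mean spanning-read depth per position (default 300, a
#'   depth at which binomial background noise stays clear of the 1%
#'   untreated cutoff).
#' @param depth_model `"poisson"` (depth ~ Poisson(mean_depth)) or
#'   `"fixed"`.
#' @param background_deletion_rate Base-independent deletion noise
#'   (default 0.001).
#' @param heterogeneity_rate Fraction of positions carrying strain-variant
#'   indels (default 0; microbiome stress-testing).
#' @param heterogeneity_del_rate Deletion rate added at heterogeneity
#'   positions in both treated and untreated samples (default 0.05).
#' @param n_replicates Biological replicates per condition (default 2).
#' @param conditions Character vector of growth conditions (default
#'   `"37C"`).
#' @param genotypes Character vector of strains; `"WT"` plus optional PUS
#'   knockouts whose names must appear in `pus_names`.
#' @param pus_names Optional PUS labels assigned uniformly to planted
#'   sites; a knockout genotype silences its sites.
#' @param plant_strand `"gene"` (sites on the strand of their host gene) or
#'   `"plus"` (all sites at plus-strand uridines, i.e. reference T).
#' @param gene_coverage Fraction of the genome covered by genes
#'   (default 0.8).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       gc_content = 0.5,
                       n_genes = 100L,
                       n_psi_sites = 1000L,
                       stoichiometry = c(0.05, 0.6),
                       mean_depth = 300,
                       depth_model = c("poisson", "fixed"),
                       background_deletion_rate = 0.001,
                       heterogeneity_rate = 0,
                       heterogeneity_del_rate = 0.05,
                       n_replicates = 2L,
                       conditions = "37C",
                       genotypes = "WT",
                       pus_names = NULL,
                       plant_strand = c("gene", "plus"),
                       gene_coverage = 0.8) {
  depth_model <- match.arg(depth_model)
  plant_strand <- match.arg(plant_strand)
  stopifnot(genome_length >= 1000, gc_content > 0, gc_content < 1,
            background_deletion_rate >= 0, background_deletion_rate < 1,
            mean_depth > 0, n_replicates >= 1)
  if (max(stoichiometry) + background_deletion_rate > 1) {
    stop_data("stoichiometry + background deletion rate exceeds 1")
  }
  ko <- setdiff(genotypes, "WT")
  if (length(ko) && !all(ko %in% (pus_names %||% character()))) {
    stop_data("knockout genotypes must be named in pus_names")
  }
  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    gc_content = gc_content, n_genes = as.integer(n_genes),
    n_psi_sites = as.integer(n_psi_sites), stoichiometry = stoichiometry,
    mean_depth = mean_depth, depth_model = depth_model,
    background_deletion_rate = background_deletion_rate,
    heterogeneity_rate = heterogeneity_rate,
    heterogeneity_del_rate = heterogeneity_del_rate,
    n_replicates = as.integer(n_replicates), conditions = conditions,
    genotypes = genotypes, pus_names = pus_names,
    plant_strand = plant_strand, gene_coverage = gene_coverage),
    class = "sim_config")
}

#' Simulate a reference genome and gene annotation
#'
#' Bases are drawn i.i.d. at the configured GC content; genes tile the
#' genome without overlap, strands assigned at random.
#'
#' @param config A [sim_config()].
#' @return List with `sequences` (named character vector, one contig
#'   `chr1`) and `annotation` (an [annotation_set()]).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gc <- config$gc_content
  bases <- sample(c("A", "C", "G", "T"), config$genome_length,
                  replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  seqs <- c(chr1 = paste(bases, collapse = ""))
  span <- config$genome_length %/% config$n_genes
  gene_len <- floor(span * config$gene_coverage)
  if (gene_len < 1L) stop_data("infeasible gene layout: genes shorter than 1 nt")
  starts <- (seq_len(config$n_genes) - 1L) * span + 1L
  ann <- annotation_set(
    gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
    ref = "chr1", start = starts, end = starts + gene_len - 1L,
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE))
  list(sequences = seqs, annotation = ann)
}

#' Plant ground-truth Psi sites
#'
#' Chooses `n_psi_sites` uridine positions (reference T on `+`, A on `-`)
#' and assigns each a stoichiometry (and a PUS label when `pus_names` is
#' set). With `plant_strand = "gene"` sites live on the strand of their
#' host gene; with `"plus"` all sites are plus-strand uridines.
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()].
#' @return The truth table: `ref`, `pos`, `strand`, `gene_id`,
#'   `stoichiometry`, `pus`.
#' @export
simulate_truth <- function(config, reference) {
  set.seed(config$seed + 1L)
  seqc <- reference$sequences[["chr1"]]
  chars <- strsplit(seqc, "")[[1L]]
  ann <- reference$annotation
  if (config$plant_strand == "plus") {
    cand_pos <- which(chars == "T")
    cand_strand <- rep("+", length(cand_pos))
  } else {
    cand_pos <- integer(); cand_strand <- character()
    for (i in seq_len(nrow(ann))) {
      want <- if (ann$strand[i] == "+") "T" else "A"
      p <- ann$start[i]:ann$end[i]
      p <- p[chars[p] == want]
      cand_pos <- c(cand_pos, p)
      cand_strand <- c(cand_strand, rep(ann$strand[i], length(p)))
    }
  }
  if (length(cand_pos) < config$n_psi_sites) {
    stop_data("not enough uridine positions to plant ", config$n_psi_sites,
              " sites")
  }
  pick <- sort(sample.int(length(cand_pos), config$n_psi_sites))
  pos <- cand_pos[pick]; strand <- cand_strand[pick]
  stoich <- if (length(config$stoichiometry) == 1L) {
    rep(config$stoichiometry, config$n_psi_sites)
  } else {
    stats::runif(config$n_psi_sites, config$stoichiometry[1L],
                 config$stoichiometry[2L])
  }
  gidx <- findInterval(pos, ann$start)
  gene_id <- ifelse(gidx >= 1 & pos <= ann$end[pmax(gidx, 1L)],
                    ann$gene_id[pmax(gidx, 1L)], NA_character_)
  pus <- if (is.null(config$pus_names)) NA_character_
         else sample(config$pus_names, config$n_psi_sites, replace = TRUE)
  data.frame(ref = "chr1", pos = pos, strand = strand, gene_id = gene_id,
             stoichiometry = stoich, pus = pus, stringsAsFactors = FALSE)
}

## genomic strain-variant positions, shared across all samples of a dataset
heterogeneity_positions <- function(config) {
  set.seed(config$seed + 2L)
  n <- round(config$heterogeneity_rate * config$genome_length)
  if (n == 0L) return(integer())
  sort(sample.int(config$genome_length, n))
}

#' Simulate one pileup table
#'
#' Per-position depth is Poisson (or fixed) at `mean_depth`; deletion
#' counts are binomial with probability background (+ stoichiometry at
#' planted sites when `treated`, + the heterogeneity rate at strain-variant
#' positions in both halves). A PUS-knockout genotype silences the planted
#' sites labelled with that PUS.
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()].
#' @param truth Output of [simulate_truth()]; `NULL` plants nothing.
#' @param treated Logical: bisulfite-treated half?
#' @param genotype Strain label (default `"WT"`).
#' @param sample_seed Seed for this sample's counts (derive distinct seeds
#'   per sample from `config$seed`).
#' @param het_pos Integer vector of heterogeneity positions (defaults to
#'   [sim_config()]'s own deterministic draw).
#' @param sample_id Sample identifier.
#' @return A [pileup_table()] covering every reference position.
#' @export
simulate_pileup <- function(config, reference, truth = NULL, treated = TRUE,
                            genotype = "WT",
                            sample_seed = config$seed + 100L,
                            het_pos = heterogeneity_positions(config),
                            sample_id = "sim") {
  set.seed(sample_seed)
  n <- config$genome_length
  chars <- strsplit(reference$sequences[["chr1"]], "")[[1L]]
  depth <- if (config$depth_model == "poisson") {
    stats::rpois(n, config$mean_depth)
  } else {
    rep(as.integer(round(config$mean_depth)), n)
  }
  p_del <- rep(config$background_deletion_rate, n)
  if (length(het_pos)) {
    p_del[het_pos] <- p_del[het_pos] + config$heterogeneity_del_rate
  }
  if (treated && !is.null(truth) && nrow(truth)) {
    active <- truth
    if (genotype != "WT") {
      active <- active[is.na(active$pus) | active$pus != genotype, ,
                       drop = FALSE]
    }
    p_del[active$pos] <- p_del[active$pos] + active$stoichiometry
  }
  if (any(p_del > 1)) stop_data("total deletion probability exceeds 1")
  del <- stats::rbinom(n, depth, p_del)
  pileup_table(ref = rep("chr1", n), pos = seq_len(n), base = chars,
               depth = depth, del_count = del, sample_id = sample_id)
}

#' Simulate a full paired-sample dataset
#'
#' Generates the reference, annotation, truth table, heterogeneity
#' positions, and one treated + one untreated pileup per
#' condition x replicate x genotype, with a sample metadata table. Output
#' is fully determined by the configuration (including its seed).
#'
#' @param config A [sim_config()].
#' @return A list: `reference`, `annotation`, `truth`, `samples` (named
#'   list of [pileup_table()]s), `meta` (`data.frame` with `sample_id`,
#'   `treated`, `condition`, `replicate`, `genotype`).
#' @export
simulate_dataset <- function(config) {
  reference <- simulate_reference(config)
  truth <- simulate_truth(config, reference)
  het <- heterogeneity_positions(config)
  grid <- expand.grid(condition = config$conditions,
                      replicate = seq_len(config$n_replicates),
                      genotype = config$genotypes,
                      treated = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  samples <- vector("list", nrow(grid))
  ids <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ids[i] <- sprintf("%s_%s_rep%d_%s", grid$genotype[i], grid$condition[i],
                      grid$replicate[i],
                      if (grid$treated[i]) "BS" else "untx")
    samples[[i]] <- simulate_pileup(
      config, reference, truth, treated = grid$treated[i],
      genotype = grid$genotype[i],
      sample_seed = config$seed + 100L + i, het_pos = het,
      sample_id = ids[i])
  }
  names(samples) <- ids
  meta <- data.frame(sample_id = ids, treated = grid$treated,
                     condition = grid$condition, replicate = grid$replicate,
                     genotype = grid$genotype, stringsAsFactors = FALSE)
  list(reference = reference$sequences, annotation = reference$annotation,
       truth = truth, samples = samples, meta = meta)
}
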