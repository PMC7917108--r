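# Synthetic-data generators with planted ground truth. Every generated
# object is re-verified against the consuming module's own predicate
# before it is returned, so the emitted truth tables cannot disagree
# with the pipeline. All output is a pure function of the seed.

#' Simulation parameters
#'
#' Defaults emulate the study design the package targets: a five-stage
#' (control + four heating durations) by three-replicate FPKM matrix,
#' a toy annotated genome, planted coexpressed lncRNA-mRNA pairs, miRNA
#' decoy sites (rule-conformant and single-rule violators), and a small
#' multi-species lncRNA panel. The scale (200 coding genes, 30 lncRNAs
#' per positional class, 100 planted trans pairs, 10 miRNAs, 5 species)
#' keeps a full end-to-end run well under a minute.
#'
#' @param seed Integer seed; all generator output is deterministic in
#'   it.
#' @param n_genes Number of protein-coding genes.
#' @param n_lnc_per_class Planted lncRNAs per positional class.
#' @param n_fail_per_kind Planted filter violators per failure kind.
#' @param genome_len Toy genome length (nt).
#' @param n_stages,n_reps Expression design (max 5 stages).
#' @param n_planted_trans_pairs Coexpressed lncRNA-mRNA pairs to plant.
#' @param noise_sd Log2-scale s.d. of multiplicative expression noise.
#' @param n_mirnas miRNAs (each with one conformant decoy site and one
#'   violator per rule).
#' @param n_species,n_families,n_lnc_per_species Conservation panel.
#' @param mutation_rate Per-base mutation rate of planted homologs
#'   (0-0.05).
#' @return List of class `sim_params`.
#' @export
sim_params <- function(seed = 1, n_genes = 200, n_lnc_per_class = 30,
                       n_fail_per_kind = 10, genome_len = 1e7,
                       n_stages = 5, n_reps = 3,
                       n_planted_trans_pairs = 100, noise_sd = 0.05,
                       n_mirnas = 10, n_species = 5, n_families = 8,
                       n_lnc_per_species = 20, mutation_rate = 0.02) {
  stopifnot(seed == floor(seed), n_stages >= 2, n_stages <= 5,
            n_reps >= 2, noise_sd >= 0, mutation_rate >= 0,
            mutation_rate <= 0.05, n_species >= 2)
  structure(as.list(environment()), class = "sim_params")
}

rand_seq <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")
# a base guaranteed to neither Watson-Crick nor wobble pair
mm_base <- c(A = "G", C = "A", G = "A", T = "C")

#' Simulate an annotated toy genome with planted lncRNA classes
#'
#' Lays out protein-coding genes (three exons, two introns) on one
#' chromosome and plants candidate transcripts of known fate: true
#' lncRNAs of each positional class (lincRNA, incRNA, lncNAT) that pass
#' every filter, plus violators for each filter step (too short;
#' mono-exonic low-expression; same-strand coding-exon overlap; coding
#' by label). Planted classes are re-verified with the package's own
#' classifier before the truth table is emitted.
#'
#' @param p A [sim_params()] list.
#' @return List with `genes` (reference annotation tibble),
#'   `transcripts` (candidate tibble), `coding_labels` (named vector),
#'   and `truth` (tibble: `transcript_id`, `expected_outcome`,
#'   `expected_class`, `low_expression`).
#' @export
simulate_annotation <- function(p = sim_params()) {
  set.seed(p$seed)
  slot <- p$genome_len %/% (p$n_genes + 1)
  n_planted <- 3 * p$n_lnc_per_class + 4 * p$n_fail_per_kind
  if (n_planted > p$n_genes || slot < 40000)
    abort("genome too small for the requested features")

  gene_start <- (seq_len(p$n_genes) - 1) * slot + 1000
  gene_strand <- rep(c("+", "-"), length.out = p$n_genes)
  mk_exons <- function(s) tibble(start = s + c(0, 2400, 4800),
                                 end = s + c(400, 2800, 5200))
  genes <- tibble(
    transcript_id = sprintf("GENE_%04d.t1", seq_len(p$n_genes)),
    gene_id = sprintf("GENE_%04d", seq_len(p$n_genes)),
    chrom = "chr1",
    start = gene_start, end = gene_start + 5200,
    strand = gene_strand,
    biotype = "protein_coding",
    exons = lapply(gene_start, mk_exons))
  genes$n_exons <- 3L
  genes$length <- vapply(genes$exons, function(e)
    sum(e$end - e$start), numeric(1))

  slot_i <- 0
  next_slot <- function() { slot_i <<- slot_i + 1; slot_i }
  cand <- list(); truth <- list()
  add <- function(id, start, exons, strand, outcome, class = NA,
                  low_expr = FALSE) {
    ex_start <- start + exons$start
    ex_end <- start + exons$end
    ex <- tibble(start = ex_start, end = ex_end)
    cand[[length(cand) + 1]] <<- tibble(
      transcript_id = id, gene_id = id, chrom = "chr1",
      start = min(ex$start), end = max(ex$end), strand = strand,
      biotype = "assembled", exons = list(ex),
      n_exons = nrow(ex),
      length = sum(ex$end - ex$start))
    truth[[length(truth) + 1]] <<- tibble(
      transcript_id = id, expected_outcome = outcome,
      expected_class = class, low_expression = low_expr)
  }
  two_ex <- tibble(start = c(0, 500), end = c(300, 800))

  for (i in seq_len(p$n_lnc_per_class)) {
    g <- next_slot()
    s <- gene_start[g]
    # intergenic, well clear of any gene span
    add(sprintf("LNC_LINC_%03d", i), s + 20000, two_ex,
        sample(c("+", "-"), 1), "retained", "lincRNA")
    g <- next_slot(); s <- gene_start[g]
    # wholly inside intron 2 (s+2800 .. s+4800), either strand
    add(sprintf("LNC_INC_%03d", i), s + 2900,
        tibble(start = c(0, 500), end = c(300, 700)),
        sample(c("+", "-"), 1), "retained", "incRNA")
    g <- next_slot(); s <- gene_start[g]
    # first exon overlaps exon 3 (s+4800 .. s+5200), opposite strand
    add(sprintf("LNC_NAT_%03d", i), s + 4900, two_ex,
        if (gene_strand[g] == "+") "-" else "+", "retained", "lncNAT")
  }
  for (i in seq_len(p$n_fail_per_kind)) {
    g <- next_slot(); s <- gene_start[g]
    add(sprintf("FAIL_LEN_%03d", i), s + 20000,
        tibble(start = c(0, 200), end = c(80, 270)),
        "+", "fail_length")
    g <- next_slot(); s <- gene_start[g]
    add(sprintf("FAIL_EXPR_%03d", i), s + 20000,
        tibble(start = 0, end = 500), "+", "fail_expression",
        low_expr = TRUE)
    g <- next_slot(); s <- gene_start[g]
    # same-strand twin of the lncNAT geometry
    add(sprintf("FAIL_OVL_%03d", i), s + 4900, two_ex,
        gene_strand[g], "fail_overlap")
    g <- next_slot(); s <- gene_start[g]
    add(sprintf("FAIL_CDS_%03d", i), s + 20000,
        tibble(start = c(0, 500), end = c(400, 1000)),
        "+", "fail_coding")
  }
  transcripts <- bind_rows(cand)
  truth <- bind_rows(truth)
  coding_labels <- setNames(
    if_else(truth$expected_outcome == "fail_coding", "coding",
            "noncoding"),
    truth$transcript_id)

  # internal consistency: the package's own classifier must agree with
  # every planted class before the truth table leaves the generator
  planted <- transcripts[match(
    truth$transcript_id[truth$expected_outcome == "retained"],
    transcripts$transcript_id), ]
  got <- classify_lncrnas(planted, genes)$positional_class
  stopifnot(identical(
    got, truth$expected_class[truth$expected_outcome == "retained"]))

  list(genes = genes, transcripts = transcripts,
       coding_labels = coding_labels, truth = truth)
}

sim_stages <- function(p) c("control", "T1", "T4", "T8", "T12")[
  seq_len(p$n_stages)]

sim_profiles <- function(p) {
  list(early_spike = c(0.5, 4.5, 3.5, 2.5, 2.0)[seq_len(p$n_stages)],
       early_drop = c(3.5, 1.0, 1.2, 1.5, 1.8)[seq_len(p$n_stages)],
       late_rise = c(1.0, 1.2, 1.8, 2.5, 3.2)[seq_len(p$n_stages)])
}

#' Simulate a stage-by-replicate FPKM matrix with planted structure
#'
#' Assigns each planted trans pair a shared stage profile drawn from a
#' small library (early-spike, early-drop, late-rise -- the response
#' shapes of heat-shock and ABA-receptor genes), all other features a
#' flat baseline; adds multiplicative log-normal noise of s.d.
#' `noise_sd` on the log2(FPKM+1) scale and truncates at zero. Features
#' flagged low-expression get a baseline whose maximum FPKM stays below
#' the mono-exonic reliability cutoff.
#'
#' @param lncrna_ids,mrna_ids Feature ids to simulate.
#' @param p A [sim_params()] list.
#' @param low_expression Ids to keep below 2 FPKM everywhere.
#' @param pair_lnc Pool of lncRNA ids eligible for pair planting
#'   (default: all `lncrna_ids` not flagged low-expression).
#' @return List with `expr` (an `fpkm_tbl`) and `truth`:
#'   `trans_pairs` (tibble `lncrna_id`, `mrna_id`, `profile`),
#'   `de` (tibble `feature_id`, `comparison` for planted
#'   >= 2-fold stage shifts), `profiles` (feature -> profile name).
#' @export
simulate_expression <- function(lncrna_ids, mrna_ids, p = sim_params(),
                                low_expression = character(),
                                pair_lnc = NULL) {
  set.seed(p$seed + 1L)
  stages <- sim_stages(p)
  profs <- sim_profiles(p)
  pool <- pair_lnc %||% setdiff(lncrna_ids, low_expression)
  n_pairs <- min(p$n_planted_trans_pairs, length(pool),
                 length(mrna_ids))
  pair_lnc <- sample(pool, n_pairs)
  pair_mrna <- sample(mrna_ids, n_pairs)
  pair_prof <- names(profs)[rep(seq_along(profs),
                                length.out = n_pairs)]
  feats <- unique(c(lncrna_ids, mrna_ids))
  prof_of <- setNames(rep("flat", length(feats)), feats)
  prof_of[pair_lnc] <- pair_prof
  prof_of[pair_mrna] <- pair_prof
  prof_of[low_expression] <- "low"

  base <- setNames(round(runif(length(feats), 0.8, 2.5), 3), feats)
  mu <- t(vapply(feats, function(f) {
    switch(prof_of[[f]],
           low = rep(0.5, length(stages)),
           flat = rep(base[[f]], length(stages)),
           profs[[prof_of[[f]]]])
  }, numeric(length(stages))))
  colnames(mu) <- stages

  sample_ids <- as.vector(outer(stages, seq_len(p$n_reps),
                                function(s, r) paste0(s, "_", r)))
  sample_ids <- sort(sample_ids)
  sample_stage <- sub("_.*$", "", sample_ids)
  eps <- matrix(rnorm(length(feats) * length(sample_ids),
                      sd = p$noise_sd),
                nrow = length(feats))
  vals <- 2^(mu[, sample_stage, drop = FALSE] + eps) - 1
  vals[vals < 0] <- 0
  rownames(vals) <- feats
  colnames(vals) <- sample_ids
  expr <- fpkm_matrix(vals,
                      samples = tibble(sample_id = sample_ids,
                                       stage = sample_stage,
                                       replicate = sub("^.*_", "",
                                                       sample_ids)),
                      stage_order = stages)
  if (length(low_expression) > 0)
    stopifnot(max(vals[low_expression, ]) < 2)

  de <- bind_rows(lapply(setdiff(stages, "control"), function(s) {
    d <- abs(mu[, s] - mu[, "control"])
    tibble(feature_id = feats[d >= 1],
           comparison = paste0(s, "_vs_control"))
  }))
  list(expr = expr,
       truth = list(
         trans_pairs = tibble(lncrna_id = pair_lnc,
                              mrna_id = pair_mrna,
                              profile = pair_prof),
         de = de,
         profiles = tibble(feature_id = feats,
                           profile = unname(prof_of))))
}

# Build the site (5'->3') pairing a miRNA whose partner vector is
# `partners` (partner of miRNA position i), with `bulge_len` extra
# target bases inserted between the partners of positions k and k+1.
site_from_partners <- function(partners, bulge_k = NA, bulge_len = 0,
                               bulge_bases = character()) {
  L <- length(partners)
  if (bulge_len == 0) return(paste(rev(partners), collapse = ""))
  paste(c(rev(partners[(bulge_k + 1):L]), bulge_bases,
          rev(partners[1:bulge_k])), collapse = "")
}

#' Simulate miRNA / lncRNA / mRNA sets with planted decoy and target
#' sites
#'
#' For each miRNA, plants one rule-conformant decoy site (legal bulge,
#' perfect seed, mismatches within bounds, strong hybridization energy)
#' in a dedicated lncRNA, and one site per rule that violates exactly
#' that rule (seed mismatch; oversized bulge; five mismatches; weak
#' energy), each in its own lncRNA; plus one perfect-complement target
#' site per miRNA in a dedicated mRNA. Every planted site is verified
#' against the package's own duplex search and decoy rules before
#' emission (resampling flanks/composition as needed).
#'
#' @param p A [sim_params()] list.
#' @return List with `mirnas`, `lncrnas`, `mrnas` (named sequence
#'   vectors), and `truth`: `decoys` (tibble `lncrna_id`, `mirna_id`,
#'   `site_start`, `kind`, `violated_rule`) and `targets` (tibble
#'   `mrna_id`, `mirna_id`, `site_start`, `expectation`).
#' @export
simulate_cerna <- function(p = sim_params()) {
  set.seed(p$seed + 2L)
  mirnas <- character(0); lncrnas <- character(0); mrnas <- character(0)
  decoy_truth <- list(); target_truth <- list()
  flank <- function(n) rand_seq(n, prob = c(0.3, 0.2, 0.2, 0.3))

  for (j in seq_len(p$n_mirnas)) {
    ok <- FALSE
    for (try in 1:200) {
      # GC-rich 5' half (strong stacks), A/T-only 3' tail: the full
      # complement is strong while a 4-mismatch GC-half site is not
      mir <- c(sample(c("A", "C", "G", "T"), 12, replace = TRUE,
                      prob = c(0.08, 0.42, 0.42, 0.08)),
               sample(c("A", "T"), 9, replace = TRUE))
      partners <- unname(comp_base[mir])
      sites <- list(
        conformant = site_from_partners(partners, 10, 3,
                                        sample(c("A", "C", "G", "T"), 3,
                                               replace = TRUE)),
        seed = site_from_partners(
          replace(partners, 5, mm_base[[mir[5]]])),
        bulge = site_from_partners(partners, 10, 5,
                                   sample(c("A", "C", "G", "T"), 5,
                                          replace = TRUE)),
        mm = site_from_partners(
          replace(partners, 14:18, mm_base[mir[14:18]])),
        energy = site_from_partners(
          replace(partners, 9:12, mm_base[mir[9:12]])))
      hosts <- lapply(sites, function(s)
        paste0(flank(100), s, flank(100)))
      mirna_seq <- paste(mir, collapse = "")
      verdicts <- lapply(hosts, function(h)
        decoy_filter(duplex_search(mirna_seq, h)))
      n_acc <- vapply(verdicts, function(v) sum(v$accepted), numeric(1))
      reason_at <- function(v, start) {
        hit <- v[v$site_start == start & !v$accepted, , drop = FALSE]
        if (nrow(hit) == 0) "" else
          hit$rejection_reasons[which.min(hit$mfe_kcal_mol)]
      }
      ok <- n_acc[["conformant"]] >= 1 &&
        all(n_acc[c("seed", "bulge", "mm", "energy")] == 0) &&
        reason_at(verdicts$seed, 101) == "seed_violation" &&
        reason_at(verdicts$mm, 101) == "mismatch_count" &&
        reason_at(verdicts$energy, 101) == "energy"
      if (ok) break
    }
    if (!ok) abort("could not construct a consistent decoy fixture")
    id <- sprintf("miR%03d", j)
    mirnas[id] <- mirna_seq
    kinds <- c("conformant", "seed", "bulge", "mm", "energy")
    rules <- c(NA, "seed_violation", "bulge", "mismatch_count",
               "energy")
    for (i in seq_along(kinds)) {
      lid <- if (kinds[i] == "conformant")
        sprintf("LNC_DECOY_%03d", j)
      else sprintf("LNC_VIOL_%s_%03d", kinds[i], j)
      lncrnas[lid] <- hosts[[kinds[i]]]
      decoy_truth[[length(decoy_truth) + 1]] <- tibble(
        lncrna_id = lid, mirna_id = id, site_start = 101L,
        site_end = 100L + nchar(sites[[kinds[i]]]),
        kind = kinds[i], violated_rule = rules[i])
    }
    gid <- sprintf("MRNA_%03d", j)
    mrnas[gid] <- paste0(flank(200), revcomp_dna(mirna_seq),
                         flank(200))
    stopifnot(expectation_score(
      mirna_seq, substr(mrnas[[gid]], 201, 200 + nchar(mirna_seq))) == 0)
    target_truth[[length(target_truth) + 1]] <- tibble(
      mrna_id = gid, mirna_id = id, site_start = 201L,
      expectation = 0)
  }
  list(mirnas = mirnas, lncrnas = lncrnas, mrnas = mrnas,
       truth = list(decoys = bind_rows(decoy_truth),
                    targets = bind_rows(target_truth)))
}

mutate_seq <- function(seq, rate) {
  if (rate == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

#' Simulate multi-species lncRNA sets with planted homologies and
#' precursor families
#'
#' Builds `n_species` lncRNA panels: species 1 is the reference; a
#' fixed block of its sequences is copied into every other species with
#' light mutation (planted homologs). Each miRNA precursor family gets
#' a random hairpin embedded in a dedicated host lncRNA in the species
#' where the family is planted: one family present in all species, a
#' block of families shared by species 1-3 only, and the rest unique to
#' single species, so common/unique accounting has known answers. The
#' planted presence matrix is re-verified with the package's own
#' precursor scan before emission.
#'
#' @param p A [sim_params()] list.
#' @return List with `species` (named list of named sequence vectors),
#'   `hairpins` (named vector, names `FAMILY_ref`), and `truth`:
#'   `homologs` (tibble `query_id`, `subject_id`, `subject_species`)
#'   and `presence` (tibble `family`, `species`).
#' @export
simulate_species_sets <- function(p = sim_params()) {
  stopifnot(p$n_species >= 2)
  set.seed(p$seed + 3L)
  sp <- sprintf("sp%d", seq_len(p$n_species))
  n_hom <- min(6, p$n_lnc_per_species)
  species <- list()
  species[[sp[1]]] <- setNames(
    vapply(seq_len(p$n_lnc_per_species),
           function(i) rand_seq(sample(300:400, 1)), character(1)),
    sprintf("%s_lnc%02d", sp[1], seq_len(p$n_lnc_per_species)))
  homologs <- list()
  for (s in sp[-1]) {
    seqs <- character(p$n_lnc_per_species)
    for (i in seq_len(p$n_lnc_per_species)) {
      if (i <= n_hom) {
        seqs[i] <- mutate_seq(species[[sp[1]]][[i]], p$mutation_rate)
        homologs[[length(homologs) + 1]] <- tibble(
          query_id = names(species[[sp[1]]])[i],
          subject_id = sprintf("%s_lnc%02d", s, i),
          subject_species = s)
      } else seqs[i] <- rand_seq(sample(300:400, 1))
    }
    species[[s]] <- setNames(seqs, sprintf("%s_lnc%02d", s,
                                           seq_len(p$n_lnc_per_species)))
  }

  fams <- sprintf("MIR%03d", seq_len(p$n_families))
  hairpins <- setNames(
    vapply(fams, function(f) rand_seq(100), character(1)),
    paste0(fams, "_ref"))
  plan <- vector("list", p$n_families)
  plan[[1]] <- sp
  shared <- seq(2, min(3, p$n_families))
  for (i in shared) plan[[i]] <- sp[seq_len(min(3, p$n_species))]
  rest <- setdiff(seq_len(p$n_families), c(1, shared))
  for (i in seq_along(rest))
    plan[[rest[i]]] <- sp[((i - 1) %% p$n_species) + 1]
  presence <- bind_rows(lapply(seq_len(p$n_families), function(i)
    tibble(family = fams[i], species = plan[[i]])))
  for (r in seq_len(nrow(presence))) {
    s <- presence$species[r]; f <- presence$family[r]
    host <- paste0(rand_seq(80), hairpins[[paste0(f, "_ref")]],
                   rand_seq(80))
    species[[s]][[sprintf("%s_host_%s", s, f)]] <- host
  }

  # re-verify: the scan over every species must reproduce the plan
  found <- bind_rows(lapply(sp, function(s) {
    rec <- precursor_scan(species[[s]], hairpins)
    if (nrow(rec) == 0) tibble(family = character(),
                               species = character())
    else distinct(tibble(family = rec$family, species = s))
  }))
  stopifnot(identical(
    arrange(found, .data$family, .data$species),
    arrange(distinct(presence), .data$family, .data$species)))

  list(species = species, hairpins = hairpins,
       truth = list(homologs = bind_rows(homologs),
                    presence = presence))
}
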