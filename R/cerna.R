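# miRNA decoy (endogenous target mimic) machinery: exhaustive bulged
# duplex enumeration, nearest-neighbor hybridization energy from a
# shipped stack table, the four decoy acceptance rules, the
# expectation-style miRNA->mRNA target score, and ceRNA triad assembly.
#
# Sequences are stored DNA-style (T); this module treats T as U. miRNA
# positions are always counted from the miRNA's 5' end.

pair_class_map <- c(AT = "W", TA = "W", CG = "W", GC = "W",
                    GT = "G", TG = "G")

classify_pair <- function(m_char, t_char) {
  cls <- pair_class_map[paste0(m_char, t_char)]
  cls[is.na(cls)] <- "M"
  unname(cls)
}

MM_PENALTY_KCAL <- 1.5  # interior mismatch penalty per position

the_stack_env <- new.env(parent = emptyenv())

#' Nearest-neighbor RNA stack table
#'
#' Loads the shipped Turner-2004-style RNA/RNA stacking free energies
#' (37 C, kcal/mol) plus bulge-loop initiation penalties. The table is
#' symmetric under helix reversal, and every stack of two Watson-Crick
#' pairs is negative (asserted at load).
#'
#' @return List with `stacks` (named vector keyed `"XY:ZW"` for the
#'   5' pair X:Y stacked on the pair whose bases read Z (target) and W
#'   (miRNA)), `bulge` (penalties for bulge lengths 2-4), and
#'   `mm_penalty`.
#' @export
stack_table <- function() {
  if (!is.null(the_stack_env$tbl)) return(the_stack_env$tbl)
  path <- system.file("extdata", "turner2004_rna_stacks.csv",
                      package = "lncregnet")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stacks <- setNames(df$dg_kcal_mol, paste0(df$pair5p, ":", df$pair3p))
  wc <- c("AU", "UA", "CG", "GC")
  wc_keys <- as.vector(outer(wc, wc, function(a, b) paste0(a, ":", b)))
  stopifnot(all(stacks[wc_keys] < 0))
  # helix reversal symmetry: dg(p:q) == dg(q:p)
  rev_keys <- paste0(df$pair3p, ":", df$pair5p)
  stopifnot(all(stacks[rev_keys] == df$dg_kcal_mol))
  tbl <- list(stacks = stacks,
              bulge = c(`2` = 2.8, `3` = 3.2, `4` = 3.6),
              mm_penalty = MM_PENALTY_KCAL)
  the_stack_env$tbl <- tbl
  tbl
}

# Hybridization energy for aligned character vectors.
# mchars: miRNA 5'->3'; pchars: the target base paired to each miRNA
# position; cls: W/G/M class per position; bulge between miRNA
# positions bulge_k and bulge_k+1 interrupts stacking and adds a
# length-dependent penalty. Returns 0 when no position pairs.
duplex_energy <- function(mchars, pchars, cls, bulge_k = NA,
                          bulge_len = 0) {
  if (!any(cls != "M")) return(0)
  tbl <- stack_table()
  mr <- chartr("T", "U", mchars)
  pr <- chartr("T", "U", pchars)
  L <- length(mchars)
  e <- 0
  for (i in seq_len(L - 1)) {
    if (cls[i] == "M" || cls[i + 1] == "M") next
    if (!is.na(bulge_k) && bulge_len > 0 && i == bulge_k) next
    key <- paste0(mr[i], pr[i], ":", pr[i + 1], mr[i + 1])
    e <- e + tbl$stacks[[key]]
  }
  if (bulge_len > 0) e <- e + tbl$bulge[[as.character(bulge_len)]]
  e + tbl$mm_penalty * sum(cls == "M")
}

#' Enumerate candidate miRNA:lncRNA duplexes
#'
#' Enumerates every target window of length `L + b` (miRNA length L,
#' bulge length b in {0, 2, 3, 4}) at every offset of the lncRNA, and
#' for b > 0 every bulge insertion point k in {9, 10, 11} (the bulged
#' target bases lie between the bases paired to miRNA positions k and
#' k+1, i.e. opposite the 9th-12th positions from the miRNA's 5' end).
#' The strands align antiparallel: miRNA position 1 pairs the 3'-most
#' base of the window. Each position is classed Watson-Crick (`W`), G:U
#' wobble (`G`) or mismatch (`M`), and a nearest-neighbor hybridization
#' energy is attached.
#'
#' @param mirna miRNA sequence, 5' to 3' (length >= 9; typically 19-24).
#' @param lncrna Target sequence, 5' to 3'.
#' @param bulge_lens Bulge lengths to enumerate (0 = no bulge).
#' @param bulge_points Allowed insertion points k.
#' @return Tibble, one row per candidate duplex: `site_start`,
#'   `site_end` (1-based inclusive on the lncRNA), `bulge_len`,
#'   `bulge_k` (NA when bulgeless), `pair_state` (string over W/G/M,
#'   miRNA position 1 first), `n_wc`, `n_gu`, `n_mm`, `mfe_kcal_mol`.
#' @export
duplex_search <- function(mirna, lncrna, bulge_lens = c(0, 2, 3, 4),
                          bulge_points = 9:11) {
  L <- nchar(mirna)
  if (L < 9) abort("miRNA shorter than 9 nt: bulge constraint undefined")
  mchars <- strsplit(chartr("U", "T", toupper(mirna)), "")[[1]]
  tchars <- strsplit(chartr("U", "T", toupper(lncrna)), "")[[1]]
  nt <- length(tchars)
  out <- list()
  for (b in bulge_lens) {
    ks <- if (b == 0) NA_integer_ else bulge_points
    for (k in ks) {
      W <- L + b
      if (nt < W) next
      if (!is.na(k) && k >= L) next
      offsets <- seq_len(nt - W + 1)
      # miRNA position i pairs window position W - (i-1) - b*(i > k)
      pw <- W - (seq_len(L) - 1L) -
        if (is.na(k)) 0L else b * (seq_len(L) > k)
      P <- matrix(tchars[outer(offsets - 1L, pw, "+")],
                  nrow = length(offsets))
      C <- vapply(seq_len(L),
                  function(i) classify_pair(mchars[i], P[, i]),
                  character(length(offsets)))
      C <- matrix(C, nrow = length(offsets))
      mfe <- candidate_energies(mchars, P, C, k, b)
      out[[length(out) + 1]] <- tibble(
        site_start = offsets, site_end = offsets + W - 1L,
        bulge_len = b, bulge_k = if (is.na(k)) NA_integer_ else k,
        pair_state = apply(C, 1, paste, collapse = ""),
        n_wc = rowSums(C == "W"), n_gu = rowSums(C == "G"),
        n_mm = rowSums(C == "M"),
        mfe_kcal_mol = mfe)
    }
  }
  if (length(out) == 0)
    return(tibble(site_start = integer(), site_end = integer(),
                  bulge_len = numeric(), bulge_k = integer(),
                  pair_state = character(), n_wc = numeric(),
                  n_gu = numeric(), n_mm = numeric(),
                  mfe_kcal_mol = numeric()))
  bind_rows(out) %>%
    arrange(.data$site_start, .data$bulge_len, .data$bulge_k)
}

# Vectorized duplex_energy over candidate rows of P (partners) / C
# (classes) for a fixed (bulge point, bulge length).
candidate_energies <- function(mchars, P, C, k, b) {
  tbl <- stack_table()
  L <- length(mchars)
  n <- nrow(P)
  mr <- chartr("T", "U", mchars)
  Pr <- matrix(chartr("T", "U", P), nrow = n)
  e <- numeric(n)
  for (i in seq_len(L - 1)) {
    if (!is.na(k) && b > 0 && i == k) next
    valid <- C[, i] != "M" & C[, i + 1] != "M"
    if (!any(valid)) next
    keys <- paste0(mr[i], Pr[valid, i], ":", Pr[valid, i + 1], mr[i + 1])
    e[valid] <- e[valid] + tbl$stacks[keys]
  }
  e <- e + tbl$mm_penalty * rowSums(C == "M")
  if (b > 0) e <- e + tbl$bulge[[as.character(b)]]
  e[rowSums(C != "M") == 0] <- 0
  e
}

#' Hybridization energy of one miRNA:site duplex
#'
#' Computes the nearest-neighbor energy of the duplex formed by a miRNA
#' and a target site of length `nchar(mirna) + bulge_len`: the sum of
#' stack energies over consecutive paired (W/G) positions, a bulge-loop
#' initiation penalty when a bulge is present, and a fixed penalty per
#' interior mismatch. 0 when nothing pairs.
#'
#' @param mirna miRNA sequence 5' to 3'.
#' @param site Target site sequence 5' to 3'.
#' @param bulge_k Bulge insertion point (NA = no bulge).
#' @param bulge_len Bulge length (0 = no bulge).
#' @return Energy in kcal/mol.
#' @export
duplex_mfe <- function(mirna, site, bulge_k = NA, bulge_len = 0) {
  L <- nchar(mirna)
  W <- nchar(site)
  stopifnot(W == L + bulge_len)
  mchars <- strsplit(chartr("U", "T", toupper(mirna)), "")[[1]]
  schars <- strsplit(chartr("U", "T", toupper(site)), "")[[1]]
  pw <- W - (seq_len(L) - 1L) -
    if (is.na(bulge_k) || bulge_len == 0) 0L
    else bulge_len * (seq_len(L) > bulge_k)
  pchars <- schars[pw]
  cls <- classify_pair(mchars, pchars)
  duplex_energy(mchars, pchars, cls, bulge_k, bulge_len)
}

#' Apply the four decoy acceptance rules to candidate duplexes
#'
#' A candidate decoy duplex is accepted iff all of: (i) hybridization
#' energy strictly below `mfe_max`; (ii) bulge absent, or of length 2-4
#' at an allowed insertion point (opposite miRNA positions 9-12);
#' (iii) perfect Watson-Crick pairing at miRNA positions 2-8 (G:U counts
#' as a seed violation unless `seed_allow_gu`); (iv) at most `mm_max`
#' mismatches over the pairing region (bulged target bases are not
#' counted). Every failed rule is recorded.
#'
#' @param duplexes Tibble from [duplex_search()].
#' @param mfe_max Strict energy cutoff (default -25 kcal/mol).
#' @param mm_max Maximum mismatch count (default 4).
#' @param seed_range miRNA positions that must pair perfectly
#'   (default 2:8).
#' @param seed_allow_gu Treat G:U as acceptable in the seed.
#' @return `duplexes` with logical `accepted` and `rejection_reasons`
#'   (`;`-separated among `energy`, `bulge`, `seed_violation`,
#'   `mismatch_count`; empty when accepted).
#' @export
decoy_filter <- function(duplexes, mfe_max = -25, mm_max = 4,
                         seed_range = 2:8, seed_allow_gu = FALSE) {
  d <- duplexes
  seed_ok <- vapply(d$pair_state, function(ps) {
    cls <- strsplit(ps, "")[[1]][seed_range]
    if (seed_allow_gu) all(cls %in% c("W", "G")) else all(cls == "W")
  }, logical(1))
  energy_ok <- d$mfe_kcal_mol < mfe_max
  bulge_ok <- d$bulge_len == 0 |
    (d$bulge_len %in% 2:4 & d$bulge_k %in% 9:11)
  mm_ok <- d$n_mm <= mm_max
  reasons <- mapply(function(e, b, s, m) {
    paste(c(if (!e) "energy", if (!b) "bulge",
            if (!s) "seed_violation", if (!m) "mismatch_count"),
          collapse = ";")
  }, energy_ok, bulge_ok, seed_ok, mm_ok)
  d$accepted <- energy_ok & bulge_ok & seed_ok & mm_ok
  d$rejection_reasons <- unname(reasons)
  d
}

#' Find accepted miRNA decoy sites across sequence sets
#'
#' Runs [duplex_search()] + [decoy_filter()] for every (lncRNA, miRNA)
#' pair and keeps the best accepted duplex (lowest energy, then
#' leftmost) per pair.
#'
#' @param mirnas,lncrnas Named character vectors of sequences.
#' @param ... Passed to [decoy_filter()].
#' @return Tibble of accepted decoy hits: `lncrna_id`, `mirna_id`, the
#'   duplex columns, `accepted = TRUE`.
#' @export
find_decoys <- function(mirnas, lncrnas, ...) {
  rows <- list()
  opts <- list(...)
  strict_seed <- !isTRUE(opts$seed_allow_gu)
  # with a strict seed rule, an accepted duplex requires the exact
  # reverse complement of miRNA positions 2-8 somewhere in the target;
  # pairs without it cannot produce hits and are skipped unsearched
  seed_rc <- vapply(mirnas, function(m)
    revcomp_dna(substr(chartr("U", "T", toupper(m)), 2, 8)),
    character(1))
  for (ln in names(lncrnas)) {
    for (mi in names(mirnas)) {
      if (strict_seed &&
          !grepl(seed_rc[[mi]], lncrnas[[ln]], fixed = TRUE)) next
      cand <- duplex_search(mirnas[[mi]], lncrnas[[ln]])
      if (nrow(cand) == 0) next
      cand <- decoy_filter(cand, ...)
      acc <- cand[cand$accepted, , drop = FALSE]
      if (nrow(acc) == 0) next
      best <- acc %>%
        arrange(.data$mfe_kcal_mol, .data$site_start) %>%
        dplyr::slice(1)
      rows[[length(rows) + 1]] <-
        bind_cols(tibble(lncrna_id = ln, mirna_id = mi), best)
    }
  }
  if (length(rows) == 0)
    return(tibble(lncrna_id = character(), mirna_id = character()))
  bind_rows(rows) %>% arrange(.data$lncrna_id, .data$mirna_id)
}

#' Expectation-style complementarity score of a gapless miRNA:site
#' alignment
#'
#' Penalty sum over miRNA positions: 0 per Watson-Crick pair, 0.5 per
#' G:U pair, 1 per mismatch, doubled at miRNA positions 2-13 (the
#' extended seed weighting of plant target prediction). Gaps, were they
#' allowed, would cost 2 per gapped nt; the built-in site scan is
#' gapless. Lower is better; a perfect complement scores 0.
#'
#' @param mirna miRNA sequence 5' to 3'.
#' @param site Gapless target site of the same length, 5' to 3'.
#' @return Numeric score.
#' @export
expectation_score <- function(mirna, site) {
  L <- nchar(mirna)
  stopifnot(nchar(site) == L)
  mchars <- strsplit(chartr("U", "T", toupper(mirna)), "")[[1]]
  schars <- strsplit(chartr("U", "T", toupper(site)), "")[[1]]
  cls <- classify_pair(mchars, rev(schars))
  cost <- c(W = 0, G = 0.5, M = 1)[cls]
  w <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
  sum(w * cost)
}

#' Predict miRNA target sites on mRNAs
#'
#' Gapless scan of each mRNA for miRNA target sites: every window of
#' miRNA length is scored with [expectation_score()]; the best site per
#' (mRNA, miRNA) pair is reported when its expectation is at most
#' `expectation_max` and the complementarity-scored length (the full
#' miRNA length in this gapless scan) is at least `hsp_min`. An optional
#' target-site accessibility check (`upe_max`) uses a documented proxy
#' (hybridization energy of the site against its own reverse complement,
#' sign-flipped) and is disabled by default.
#'
#' @param mirnas,mrnas Named character vectors of sequences.
#' @param expectation_max Inclusive expectation cutoff (default 3).
#' @param hsp_min Minimum scored length (default 20).
#' @param upe_max Inclusive accessibility cutoff (default 25).
#' @param check_upe Enable the accessibility proxy.
#' @return Tibble of target hits: `mrna_id`, `mirna_id`, `site_start`,
#'   `site_end`, `expectation`, `hsp_len`, `upe_proxy` (NA when
#'   disabled).
#' @export
predict_targets <- function(mirnas, mrnas, expectation_max = 3,
                            hsp_min = 20, upe_max = 25,
                            check_upe = FALSE) {
  rows <- list()
  for (gi in names(mrnas)) {
    tchars <- strsplit(chartr("U", "T", toupper(mrnas[[gi]])), "")[[1]]
    for (mi in names(mirnas)) {
      mseq <- chartr("U", "T", toupper(mirnas[[mi]]))
      L <- nchar(mseq)
      if (L < hsp_min || length(tchars) < L) next
      mchars <- strsplit(mseq, "")[[1]]
      offsets <- seq_len(length(tchars) - L + 1)
      # antiparallel: miRNA position i pairs window position L - i + 1
      w <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
      scores <- vapply(offsets, function(s) {
        part <- tchars[(s + L - 1):s]
        cls <- classify_pair(mchars, part)
        sum(w * c(W = 0, G = 0.5, M = 1)[cls])
      }, numeric(1))
      best <- which.min(scores)
      if (scores[best] > expectation_max) next
      site <- paste(tchars[best:(best + L - 1)], collapse = "")
      upe <- NA_real_
      if (check_upe) {
        upe <- -duplex_mfe(site, revcomp_dna(site))
        if (upe > upe_max) next
      }
      rows[[length(rows) + 1]] <- tibble(
        mrna_id = gi, mirna_id = mi,
        site_start = best, site_end = best + L - 1L,
        expectation = scores[best], hsp_len = L, upe_proxy = upe)
    }
  }
  if (length(rows) == 0)
    return(tibble(mrna_id = character(), mirna_id = character(),
                  site_start = integer(), site_end = integer(),
                  expectation = numeric(), hsp_len = integer(),
                  upe_proxy = numeric()))
  bind_rows(rows) %>% arrange(.data$mrna_id, .data$mirna_id)
}

#' Reverse complement of a DNA-alphabet sequence
#' @param seq Sequence over A/C/G/T/N.
#' @return Reverse complement string.
#' @export
revcomp_dna <- function(seq) {
  paste(rev(strsplit(chartr("ACGTU", "TGCAA", toupper(seq)), "")[[1]]),
        collapse = "")
}

#' Assemble ceRNA triads from decoy and target hits
#'
#' Cross-references accepted decoy (lncRNA, miRNA) pairs with accepted
#' target (miRNA, mRNA) pairs: one triad per (lncRNA, miRNA, mRNA)
#' sharing the miRNA.
#'
#' @param decoys Accepted decoy hits (see [find_decoys()]).
#' @param targets Accepted target hits (see [predict_targets()]).
#' @return List of class `cerna_network` with `triads` (tibble
#'   `lncrna_id`, `mirna_id`, `mrna_id`) and `nodes` (typed node table).
#' @export
build_triads <- function(decoys, targets) {
  triads <- inner_join(distinct(decoys, .data$lncrna_id, .data$mirna_id),
                       distinct(targets, .data$mirna_id, .data$mrna_id),
                       by = "mirna_id",
                       relationship = "many-to-many") %>%
    select("lncrna_id", "mirna_id", "mrna_id") %>%
    distinct() %>%
    arrange(.data$lncrna_id, .data$mirna_id, .data$mrna_id)
  nodes <- bind_rows(
    tibble(id = unique(triads$lncrna_id), type = "lncRNA"),
    tibble(id = unique(triads$mirna_id), type = "miRNA"),
    tibble(id = unique(triads$mrna_id), type = "mRNA")
  ) %>% arrange(.data$id)
  structure(list(triads = triads, nodes = nodes),
            class = "cerna_network")
}

#' @export
tidy.cerna_network <- function(x, ...) as_tibble(x$triads)

#' @export
glance.cerna_network <- function(x, ...) {
  tibble(n_lncrna = sum(x$nodes$type == "lncRNA"),
         n_mirna = sum(x$nodes$type == "miRNA"),
         n_mrna = sum(x$nodes$type == "mRNA"),
         n_triads = nrow(x$triads))
}

#' Write a ceRNA network as node/edge TSV files
#'
#' Edges are the lncRNA-miRNA (decoy) and miRNA-mRNA (target) legs of
#' each triad.
#'
#' @param x A `cerna_network`.
#' @param path_prefix Output prefix.
#' @return Written paths, invisibly.
#' @export
write_cerna_network <- function(x, path_prefix) {
  edges <- bind_rows(
    x$triads %>% distinct(from = .data$lncrna_id, to = .data$mirna_id) %>%
      mutate(edge_type = "decoy"),
    x$triads %>% distinct(from = .data$mirna_id, to = .data$mrna_id) %>%
      mutate(edge_type = "target")
  )
  write_network_tsv(x$nodes, edges, path_prefix)
}
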