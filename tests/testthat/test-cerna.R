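# Duplex enumeration vs an independent exhaustive oracle, the energy
# model's contracts, the four decoy rules, the expectation score, and
# triad assembly.

test_that("a perfect complement yields an all-WC bulgeless duplex", {
  set.seed(20)
  mir <- rand_dna(21)
  target <- paste0(rand_dna(50), revcomp_dna(mir), rand_dna(50))
  cand <- duplex_search(mir, target)
  hit <- cand[cand$site_start == 51 & cand$bulge_len == 0, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$pair_state, strrep("W", 21))
  expect_equal(hit$n_mm, 0)
  expect_lt(hit$mfe_kcal_mol, -20)
})

test_that("a constructed bulged site is found with the planted bulge geometry", {
  set.seed(21)
  mir_chars <- strsplit(rand_dna(21), "")[[1]]
  site <- decoy_site(unname(complement1[mir_chars]), bulge_k = 10,
                     bulge_len = 3, bulge_bases = c("A", "A", "A"))
  target <- paste0(rand_dna(40), site, rand_dna(40))
  cand <- duplex_search(paste(mir_chars, collapse = ""), target)
  hit <- cand[cand$site_start == 41 & cand$bulge_len == 3 &
                !is.na(cand$bulge_k) & cand$bulge_k == 10, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$pair_state, strrep("W", 21))
})

test_that("candidate enumeration equals an exhaustive oracle", {
  # independent construction: extract each window, delete the bulged
  # block, reverse, and classify -- no shared indexing arithmetic
  oracle <- function(mirna, target) {
    mc <- strsplit(mirna, "")[[1]]
    tc <- strsplit(target, "")[[1]]
    L <- length(mc)
    pair_of <- function(a, b) {
      ab <- paste0(a, b)
      if (ab %in% c("AT", "TA", "CG", "GC")) "W"
      else if (ab %in% c("GT", "TG")) "G" else "M"
    }
    rows <- list()
    for (b in c(0, 2, 3, 4)) {
      for (k in if (b == 0) NA else 9:11) {
        W <- L + b
        if (length(tc) < W) next
        for (s in seq_len(length(tc) - W + 1)) {
          win <- tc[s:(s + W - 1)]
          if (b > 0) {
            # bulged target bases lie between the partners of miRNA
            # positions k and k+1; counted from the window's 3' end
            # the partner of position k is the k-th base, so drop the
            # block just 5' of it
            drop <- (W - k - b + 1):(W - k)
            win <- win[-drop]
          }
          partners <- rev(win)
          cls <- vapply(seq_len(L),
                        function(i) pair_of(mc[i], partners[i]),
                        character(1))
          rows[[length(rows) + 1]] <- tibble::tibble(
            site_start = s, site_end = s + W - 1L,
            bulge_len = b,
            bulge_k = if (is.na(k)) NA_integer_ else as.integer(k),
            pair_state = paste(cls, collapse = ""))
        }
      }
    }
    dplyr::arrange(dplyr::bind_rows(rows), site_start, bulge_len,
                   bulge_k)
  }
  set.seed(22)
  for (rep in 1:3) {
    mir <- rand_dna(sample(19:24, 1))
    target <- paste0(rand_dna(30), revcomp_dna(mir), rand_dna(60))
    got <- duplex_search(mir, target)
    want <- oracle(mir, target)
    cols <- c("site_start", "site_end", "bulge_len", "bulge_k",
              "pair_state")
    expect_equal(as.data.frame(got[cols]), as.data.frame(want),
                 ignore_attr = TRUE)
    # counts are consistent with the state string
    expect_equal(got$n_mm,
                 stringr::str_count(got$pair_state, "M"))
    expect_equal(got$n_wc + got$n_gu + got$n_mm,
                 rep(nchar(mir), nrow(got)))
  }
})

test_that("energy model honours its contracts", {
  # zero paired positions -> exactly 0
  expect_equal(duplex_mfe(strrep("A", 21), strrep("A", 21)), 0)

  # all-WC duplex equals the frozen hand summation over the shipped
  # stack table (20 stacks of the fixed helix below)
  m <- "ACGTACGTACGTACGTACGTA"
  expect_equal(duplex_mfe(m, revcomp_dna(m)), -40.5)

  # strand-reversal symmetry of the helix
  set.seed(23)
  for (rep in 1:10) {
    a <- rand_dna(15)
    b <- rand_dna(15)
    expect_equal(duplex_mfe(a, b), duplex_mfe(b, a))
  }

  # appending one complementary base never raises the energy
  for (rep in 1:10) {
    a <- rand_dna(14)
    longer <- paste0(a, sample(c("A", "C", "G", "T"), 1))
    expect_lte(duplex_mfe(longer, revcomp_dna(longer)),
               duplex_mfe(a, revcomp_dna(a)))
  }
})

test_that("each decoy rule rejects in isolation and a conformant duplex passes", {
  set.seed(24)
  gc_mir <- strsplit(paste0(
    rand_dna(12, c("C", "G")), rand_dna(9, c("A", "T"))), "")[[1]]
  partners <- unname(complement1[gc_mir])
  mirna <- paste(gc_mir, collapse = "")
  run <- function(site) {
    cand <- duplex_search(mirna, paste0(rand_dna(30), site,
                                        rand_dna(30)))
    decoy_filter(cand)
  }
  # conformant: legal bulge, perfect seed, 0 mismatches, strong energy
  ok <- run(decoy_site(partners, 10, 3))
  expect_gte(sum(ok$accepted), 1)

  seed_bad <- run(decoy_site(replace(partners, 5,
                                     mismatch1[[gc_mir[5]]])))
  expect_equal(sum(seed_bad$accepted), 0)
  expect_true(any(grepl("seed_violation",
                        seed_bad$rejection_reasons[seed_bad$n_mm == 1])))

  mm_bad <- run(decoy_site(replace(partners, 14:18,
                                   mismatch1[gc_mir[14:18]])))
  expect_equal(sum(mm_bad$accepted), 0)
  expect_true(any(mm_bad$rejection_reasons[mm_bad$n_mm == 5] ==
                    "mismatch_count"))

  # weak energy: A/T-only miRNA cannot reach -25 without a GC helix
  at_mir <- rand_dna(21, c("A", "T"))
  at_partners <- unname(complement1[strsplit(at_mir, "")[[1]]])
  weak <- decoy_filter(duplex_search(
    at_mir, paste0(rand_dna(30, c("A", "C")),
                   decoy_site(at_partners),
                   rand_dna(30, c("A", "C")))))
  expect_equal(sum(weak$accepted), 0)
  full <- weak[weak$pair_state == strrep("W", 21), ]
  expect_equal(full$rejection_reasons, "energy")
  expect_gt(full$mfe_kcal_mol, -25)

  # an oversized bulge is rejected by the rule even if handed directly
  over <- tibble::tibble(site_start = 1L, site_end = 26L,
                         bulge_len = 5, bulge_k = 10L,
                         pair_state = strrep("W", 21), n_wc = 21,
                         n_gu = 0, n_mm = 0, mfe_kcal_mol = -40)
  expect_false(decoy_filter(over)$accepted)
  expect_equal(decoy_filter(over)$rejection_reasons, "bulge")
})

test_that("decoy acceptance is monotone in energy and G:U seed handling is optional", {
  d <- tibble::tibble(site_start = 1L, site_end = 21L, bulge_len = 0,
                      bulge_k = NA_integer_,
                      pair_state = strrep("W", 21), n_wc = 21,
                      n_gu = 0, n_mm = 0, mfe_kcal_mol = -26)
  expect_true(decoy_filter(d)$accepted)
  d2 <- d; d2$mfe_kcal_mol <- -60
  expect_true(decoy_filter(d2)$accepted)
  d3 <- d; d3$mfe_kcal_mol <- -25  # boundary: strict <
  expect_false(decoy_filter(d3)$accepted)

  gu_seed <- d
  gu_seed$pair_state <- paste0("WGW", strrep("W", 18))
  gu_seed$n_gu <- 1; gu_seed$n_wc <- 20
  expect_false(decoy_filter(gu_seed)$accepted)
  expect_true(decoy_filter(gu_seed, seed_allow_gu = TRUE)$accepted)
})

test_that("expectation score follows the weighted penalty scheme", {
  set.seed(25)
  mc <- strsplit(rand_dna(21), "")[[1]]
  perfect <- paste(rev(unname(complement1[mc])), collapse = "")
  expect_equal(expectation_score(paste(mc, collapse = ""), perfect), 0)

  # single G:U at position 16 (weight 1): force m16 = G, partner = T
  mc16 <- replace(mc, 16, "G")
  p16 <- replace(unname(complement1[mc16]), 16, "T")
  expect_equal(expectation_score(paste(mc16, collapse = ""),
                                 paste(rev(p16), collapse = "")), 0.5)

  # single mismatch at position 4 (seed-weighted x2)
  p4 <- replace(unname(complement1[mc]), 4, mismatch1[[mc[4]]])
  expect_equal(expectation_score(paste(mc, collapse = ""),
                                 paste(rev(p4), collapse = "")), 2)
})

test_that("target prediction applies inclusive expectation and HSP cutoffs", {
  set.seed(26)
  # force position 16 to G so a G:U can be planted there later
  mchars <- replace(strsplit(rand_dna(21), "")[[1]], 16, "G")
  mir <- c(m1 = paste(mchars, collapse = ""))
  partners <- unname(complement1[mchars])
  perfect <- paste(rev(partners), collapse = "")
  # three weight-1 mismatches -> expectation exactly 3.0
  p3 <- replace(partners, c(15, 17, 19), mismatch1[mchars[c(15, 17, 19)]])
  at3 <- paste(rev(p3), collapse = "")
  # the same plus a weight-1 G:U at position 16 -> 3.5, over the cutoff
  p35 <- replace(p3, 16, "T")
  over3 <- paste(rev(p35), collapse = "")

  mrnas <- c(hit0 = paste0(rand_dna(100), perfect, rand_dna(100)),
             hit3 = paste0(rand_dna(100), at3, rand_dna(100)),
             miss = paste0(rand_dna(100), over3, rand_dna(100)))
  hits <- predict_targets(mir, mrnas)
  expect_equal(hits$expectation[hits$mrna_id == "hit0"], 0)
  expect_equal(hits$site_start[hits$mrna_id == "hit0"], 101L)
  expect_equal(hits$expectation[hits$mrna_id == "hit3"], 3)
  expect_false("miss" %in% hits$mrna_id)
  expect_true(all(hits$hsp_len >= 20))

  # a 19-nt miRNA fails the HSP length floor outright
  short <- c(s1 = rand_dna(19))
  expect_equal(nrow(predict_targets(short, mrnas)), 0)
})

test_that("triad assembly is the shared-miRNA cross-reference", {
  decoys <- tibble::tibble(lncrna_id = c("L1", "L2"),
                           mirna_id = c("M1", "M2"))
  targets <- tibble::tibble(mirna_id = c("M1", "M3"),
                            mrna_id = c("G1", "G2"))
  net <- build_triads(decoys, targets)
  expect_equal(nrow(net$triads), 1)
  expect_equal(unlist(net$triads[1, ], use.names = FALSE),
               c("L1", "M1", "G1"))
  expect_equal(glance(net)$n_triads, 1)

  # triad count = sum over miRNAs of decoy-degree * target-degree
  set.seed(27)
  d2 <- tibble::tibble(
    lncrna_id = sample(paste0("L", 1:6), 12, TRUE),
    mirna_id = sample(paste0("M", 1:4), 12, TRUE)) |>
    dplyr::distinct()
  t2 <- tibble::tibble(
    mirna_id = sample(paste0("M", 1:4), 12, TRUE),
    mrna_id = sample(paste0("G", 1:6), 12, TRUE)) |>
    dplyr::distinct()
  n_expected <- sum(vapply(paste0("M", 1:4), function(m)
    sum(d2$mirna_id == m) * sum(t2$mirna_id == m), numeric(1)))
  expect_equal(nrow(build_triads(d2, t2)$triads), n_expected)

  prefix <- withr::local_tempfile()
  write_cerna_network(build_triads(d2, t2), prefix)
  files <- read_network_tsv(prefix)
  expect_setequal(unique(files$edges$edge_type), c("decoy", "target"))
})
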