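# cis window boundaries, trans threshold strictness (including an
# exactly-representable r = 0.95 construction), the all-pairs oracle,
# and SA/degree identities.

test_that("cis window is inclusive at the boundary and 0 on overlap", {
  # gene span 500000-505200; lncRNAs at controlled gaps
  g <- make_coding_gene("G1", 500000)
  lnc <- dplyr::bind_rows(
    make_tx("overlapping", exons = list(c(504000, 504600))),
    make_tx("at_window", exons = list(c(605200, 605800))),   # gap 100000
    make_tx("past_window", exons = list(c(605201, 605801))), # gap 100001
    make_tx("upstream_ok", exons = list(c(399500, 399900))))  # gap 100100
  edges <- cis_targets(lnc, g, window = 100000)
  expect_true("overlapping" %in% edges$lncrna_id)
  expect_equal(edges$distance_bp[edges$lncrna_id == "overlapping"], 0)
  expect_true("at_window" %in% edges$lncrna_id)
  expect_equal(edges$distance_bp[edges$lncrna_id == "at_window"],
               100000)
  expect_false("past_window" %in% edges$lncrna_id)
  expect_false("upstream_ok" %in% edges$lncrna_id)  # gap 100100

  strict <- cis_targets(lnc, g, window = 100000, exclusive = TRUE)
  expect_false("at_window" %in% strict$lncrna_id)
})

test_that("trans edges require strictly |r| > 0.95: r = 0.95 exactly is excluded", {
  # integer construction: dot = 19, |dx| * |dy| = sqrt(20 * 20) = 20,
  # so r is the correctly rounded double of 19/20 = 0.95
  x <- c(-3, -1, 0, 1, 3) + 4
  y <- c(-3, -1, 1, 0, 3) + 4
  m <- rbind(L_boundary = x, L_perfect = x, M1 = y, M2 = x)
  colnames(m) <- paste0(c("control", "T1", "T4", "T8", "T12"), "_1")
  expr <- fpkm_matrix(m)
  edges <- trans_targets(expr, c("L_boundary", "L_perfect"),
                         c("M1", "M2"), r_min = 0.95, p_max = 1)
  pairs <- paste(edges$lncrna_id, edges$mrna_id)
  expect_false("L_boundary M1" %in% pairs)  # r == 0.95, strict >
  expect_true("L_perfect M2" %in% pairs)    # r == 1
  expect_equal(edges$r[edges$lncrna_id == "L_perfect" &
                         edges$mrna_id == "M2"], 1)
})

test_that("trans edge set equals the brute-force all-pairs oracle", {
  set.seed(12)
  n_lnc <- 25; n_mrna <- 25
  ids_l <- paste0("L", seq_len(n_lnc))
  ids_m <- paste0("M", seq_len(n_mrna))
  # half the lncRNAs echo an mRNA profile so edges exist at threshold
  base <- matrix(rexp(n_mrna * 5, 0.3), n_mrna, 5)
  lncm <- matrix(rexp(n_lnc * 5, 0.3), n_lnc, 5)
  lncm[1:12, ] <- base[1:12, ] * 2^rnorm(60, sd = 0.03)
  m <- rbind(lncm, base)
  dimnames(m) <- list(c(ids_l, ids_m),
                      paste0(c("control", "T1", "T4", "T8", "T12"),
                             "_1"))
  expr <- fpkm_matrix(m)
  edges <- trans_targets(expr, ids_l, ids_m,
                         r_min = 0.95, p_max = 0.01)
  got <- sort(paste(edges$lncrna_id, edges$mrna_id))
  want <- character()
  for (l in ids_l) for (g in ids_m) {
    ct <- suppressWarnings(cor.test(m[l, ], m[g, ]))
    if (abs(ct$estimate) > 0.95 && ct$p.value < 0.01)
      want <- c(want, paste(l, g))
  }
  expect_equal(got, sort(want))
  expect_gt(length(want), 0)
})

test_that("constant features are skipped, not fatal", {
  m <- rbind(L1 = c(1, 2, 3, 4, 5), Lflat = rep(2, 5),
             M1 = c(2, 4, 6, 8, 10))
  colnames(m) <- paste0(c("control", "T1", "T4", "T8", "T12"), "_1")
  expr <- fpkm_matrix(m)
  expect_message(
    edges <- trans_targets(expr, c("L1", "Lflat"), "M1"),
    "constant")
  expect_equal(edges$lncrna_id, "L1")
})

test_that("cis/trans combination is an intersection retaining evidence", {
  cis <- tibble::tibble(lncrna_id = c("L1", "L2"),
                        mrna_id = c("M1", "M2"),
                        mode = "cis", distance_bp = c(0, 5000))
  trans <- tibble::tibble(lncrna_id = c("L1", "L3"),
                          mrna_id = c("M1", "M3"),
                          mode = "trans", r = c(0.99, 0.97),
                          p = c(1e-4, 1e-3))
  both <- combine_cis_trans(cis, trans)
  expect_equal(nrow(both), 1)
  expect_equal(both$mode, "both")
  expect_equal(both$distance_bp, 0)
  expect_equal(both$r, 0.99)
  expect_lte(nrow(both), min(nrow(cis), nrow(trans)))
  expect_equal(nrow(combine_cis_trans(cis[2, ], trans)), 0)
})

test_that("SA pairs require opposite strands and span overlap", {
  g <- make_coding_gene("G1", 10000, strand = "+")
  lnc <- dplyr::bind_rows(
    make_tx("anti_over", strand = "-",
            exons = list(c(14900, 15200), c(15400, 15700))),
    make_tx("sense_over", strand = "+",
            exons = list(c(12900, 13200))),
    make_tx("anti_far", strand = "-",
            exons = list(c(20200, 20800))))
  edges <- tibble::tibble(
    lncrna_id = c("anti_over", "sense_over", "anti_far"),
    mrna_id = "G1", mode = "cis", distance_bp = c(0, 0, 5000))
  flagged <- sa_pairs(edges, lnc, g)
  expect_equal(flagged$sa_pair, c(TRUE, FALSE, FALSE))
  # SA pairs sit among zero-distance cis edges
  expect_true(all(flagged$distance_bp[flagged$sa_pair] == 0))
})

test_that("degree tables respect the handshake identity", {
  edges <- tibble::tibble(
    lncrna_id = c("L1", "L1", "L1", "L2"),
    mrna_id = c("M1", "M2", "M3", "M1"))
  deg <- degree_tables(edges)
  expect_equal(deg$lncrna$degree[deg$lncrna$id == "L1"], 3L)
  expect_equal(sum(deg$lncrna$degree), nrow(edges))
  expect_equal(sum(deg$mrna$degree), nrow(edges))
  empty <- degree_tables(edges[0, ])
  expect_equal(nrow(empty$lncrna), 0)

  net <- reg_network(dplyr::mutate(edges, mode = "trans"))
  expect_equal(glance(net)$n_nodes, 5)
  expect_equal(nrow(tidy(net)), 4)
  prefix <- withr::local_tempfile()
  write_reg_network(net, prefix)
  expect_equal(nrow(read_network_tsv(prefix)$edges), 4)
})

test_that("planted cis/trans/SA structure is recovered exactly at zero noise", {
  p <- small_params()
  p$noise_sd <- 0
  ann <- simulate_annotation(p)
  retained_ids <-
    ann$truth$transcript_id[ann$truth$expected_outcome == "retained"]
  se <- simulate_expression(
    ann$truth$transcript_id, ann$genes$gene_id, p,
    low_expression =
      ann$truth$transcript_id[ann$truth$low_expression],
    pair_lnc = retained_ids)
  tp <- se$truth$trans_pairs
  edges <- trans_targets(se$expr, unique(tp$lncrna_id),
                         unique(tp$mrna_id))
  found <- paste(edges$lncrna_id, edges$mrna_id)
  expect_true(all(paste(tp$lncrna_id, tp$mrna_id) %in% found))
  expect_true(all(abs(edges$r[match(paste(tp$lncrna_id, tp$mrna_id),
                                    found)] - 1) < 1e-12))
})
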