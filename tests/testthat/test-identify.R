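# The screening cascade and positional classifier, on hand-built
# geometries and on the simulator's planted annotation.

genes_far <- make_coding_gene("G1", 500000)

test_that("length filter keeps 200 nt and drops 199 nt (strict 'shorter than')", {
  tx <- dplyr::bind_rows(
    make_tx("short", exons = list(c(0, 100), c(200, 299))),   # 199 nt
    make_tx("kept", exons = list(c(0, 100), c(200, 300))))    # 200 nt
  expr <- flat_expr(tx$transcript_id)
  out <- filter_candidates(tx, genes_far, expr)
  expect_equal(out$fail_step[out$transcript_id == "short"], "length")
  expect_true(out$retained[out$transcript_id == "kept"])
})

test_that("mono-exonic transcripts below the FPKM cutoff are removed", {
  tx <- dplyr::bind_rows(
    make_tx("mono_low", exons = list(c(0, 500))),
    make_tx("mono_ok", exons = list(c(1000, 1500))),
    make_tx("multi_low", exons = list(c(2000, 2300), c(2500, 2800))))
  m <- matrix(c(1.9, 1.9, 2.0, 2.0, 1.9, 1.9), nrow = 3, byrow = TRUE,
              dimnames = list(tx$transcript_id,
                              c("control_1", "T1_1")))
  out <- filter_candidates(tx, genes_far, fpkm_matrix(m))
  expect_equal(out$fail_step[out$transcript_id == "mono_low"],
               "expression")
  expect_true(out$retained[out$transcript_id == "mono_ok"])
  expect_true(out$retained[out$transcript_id == "multi_low"])
})

test_that("same-strand coding-exon overlap removes; antisense survives as lncNAT", {
  g <- make_coding_gene("G1", 10000, strand = "+")
  # first exon overlaps coding exon 3 (14800-15200) by 300 bp
  sense <- make_tx("sense", strand = "+",
                   exons = list(c(14900, 15200), c(15400, 15700)))
  anti <- make_tx("anti", strand = "-",
                  exons = list(c(14900, 15200), c(15400, 15700)))
  expr <- flat_expr(c("sense", "anti"))
  out <- identify_lncrnas(dplyr::bind_rows(sense, anti), g, expr)
  expect_equal(out$fail_step[out$transcript_id == "sense"], "overlap")
  expect_true(out$retained[out$transcript_id == "anti"])
  expect_equal(out$positional_class[out$transcript_id == "anti"],
               "lncNAT")
})

test_that("coding calls remove transcripts via labels or the ORF stand-in", {
  tx <- dplyr::bind_rows(
    make_tx("lab_cod", exons = list(c(0, 150), c(300, 500))),
    make_tx("lab_nc", exons = list(c(1000, 1150), c(1300, 1500))))
  expr <- flat_expr(tx$transcript_id)
  out <- filter_candidates(tx, genes_far, expr,
                           coding_labels = c(lab_cod = "coding",
                                             lab_nc = "noncoding"))
  expect_equal(out$fail_step[out$transcript_id == "lab_cod"], "coding")
  expect_true(out$retained[out$transcript_id == "lab_nc"])

  # ORF path: 150 aa ORF vs a stop-riddled sequence
  orf_seq <- paste0("ATG", strrep("GCA", 150), "TAA")
  junk <- paste(rep("TAATAG", 80), collapse = "")
  tx2 <- dplyr::bind_rows(
    make_tx("has_orf", exons = list(c(0, nchar(orf_seq)))),
    make_tx("no_orf", exons = list(c(5000, 5000 + nchar(junk)))))
  out2 <- filter_candidates(
    tx2, genes_far, flat_expr(tx2$transcript_id),
    seqs = c(has_orf = orf_seq, no_orf = junk))
  expect_equal(out2$fail_step[out2$transcript_id == "has_orf"],
               "coding")
  expect_true(out2$retained[out2$transcript_id == "no_orf"])
})

test_that("positional classes follow definition and precedence", {
  g <- make_coding_gene("G1", 10000, strand = "+")
  far <- make_tx("far", exons = list(c(30000, 30300), c(30500, 30800)))
  expect_equal(classify_position(far, g), "lincRNA")
  # wholly inside intron 2 (12800-14800), same strand, no exon overlap
  inc <- make_tx("inc", strand = "+",
                 exons = list(c(12900, 13200), c(13400, 13700)))
  expect_equal(classify_position(inc, g), "incRNA")
  # 50-bp antisense overlap of coding exon 1 (10000-10400)
  nat <- make_tx("nat", strand = "-",
                 exons = list(c(10350, 10700), c(10900, 11200)))
  expect_equal(classify_position(nat, g), "lncNAT")

  # precedence: inside an intron of G1 AND antisense-overlapping an
  # exon of a second gene nested there -> lncNAT wins
  g2 <- make_tx("G2.t1", strand = "+", gene_id = "G2",
                biotype = "protein_coding",
                exons = list(c(13000, 13100)))
  both <- make_tx("both", strand = "-",
                  exons = list(c(13050, 13350), c(13500, 13800)))
  expect_equal(classify_position(both, dplyr::bind_rows(g, g2)),
               "lncNAT")

  # a same-strand exon overlapper must have been filtered already
  bad <- make_tx("bad", strand = "+",
                 exons = list(c(10350, 10700)))
  expect_error(classify_position(bad, g), "filtered")
})

test_that("longest-ORF stand-in matches a brute-force scan", {
  expect_equal(orf_stand_in("ATGAAATAG"), 2L)
  expect_equal(orf_stand_in("CCCCCCCCC"), 0L)
  expect_equal(orf_stand_in("ATGAAA"), 0L)  # no stop, no ORF

  brute_orf <- function(seq) {
    chars <- strsplit(seq, "")[[1]]
    stops <- c("TAA", "TAG", "TGA")
    best <- 0L
    for (i in seq_len(max(0, length(chars) - 2))) {
      if (paste(chars[i:(i + 2)], collapse = "") != "ATG") next
      j <- i + 3
      while (j + 2 <= length(chars)) {
        codon <- paste(chars[j:(j + 2)], collapse = "")
        if (codon %in% stops) {
          best <- max(best, (j - i) / 3)
          break
        }
        j <- j + 3
      }
    }
    as.integer(best)
  }
  set.seed(11)
  for (rep in 1:5) {
    s <- rand_dna(1000)
    expect_equal(orf_stand_in(s), brute_orf(s))
  }
})

test_that("classification partitions survivors and filters are monotone in min_length", {
  p <- small_params()
  ann <- simulate_annotation(p)
  se <- simulate_expression(
    ann$truth$transcript_id, ann$genes$gene_id, p,
    low_expression = ann$truth$transcript_id[ann$truth$low_expression])
  cat <- identify_lncrnas(ann$transcripts, ann$genes, se$expr,
                          coding_labels = ann$coding_labels)
  kept <- cat[cat$retained, ]
  expect_true(all(kept$positional_class %in%
                    c("lincRNA", "incRNA", "lncNAT")))
  g <- glance(cat)
  expect_equal(g$n_lincRNA + g$n_incRNA + g$n_lncNAT, g$n_lncrna)

  n_kept <- vapply(c(100, 200, 400, 700, 1200), function(len) {
    sum(filter_candidates(ann$transcripts, ann$genes, se$expr,
                          filter_params(min_length = len),
                          coding_labels = ann$coding_labels)$retained)
  }, numeric(1))
  expect_true(all(diff(n_kept) <= 0))
})
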