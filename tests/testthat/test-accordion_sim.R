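test_that("branch event counts follow the Poisson law", {
  cfg0 <- accordion_config(rates = c(duplication = 0, loss = 0))
  expect_equal(nrow(draw_branch_events(cfg0, 5)), 0)

  cfg <- accordion_config(rates = c(duplication = 2))
  expect_equal(nrow(draw_branch_events(cfg, 0)), 0)
  expect_error(draw_branch_events(cfg, -1),
               class = "gvaccordion_domain_error")

  set.seed(11)
  counts <- replicate(10000, nrow(draw_branch_events(cfg, 1)))
  expect_gt(mean(counts), 1.95) # 2 +/- ~4 standard errors
  expect_lt(mean(counts), 2.05)
  # times sorted along the branch
  ev <- draw_branch_events(cfg, 3)
  expect_false(is.unsorted(ev$t))
  expect_true(all(ev$t >= 0 & ev$t <= 3))
})

test_that("event application follows the accordion semantics", {
  genes <- tibble::tibble(
    gene_id = sprintf("g%d", 1:5),
    family_id = c("F1", "F2", "F2", "M1", "F3"),
    start = c(200L, 1400L, 2600L, 3800L, 5000L),
    end = c(1200L, 2400L, 3600L, 4800L, 6000L),
    strand = "+", flags = c("", "", "", "MGE", ""))
  g <- genome_record(genes, "test")

  # loss of a single-copy family removes it entirely
  g1 <- apply_event(g, list(event_type = "loss", family_id = "F1",
                            gene_id = "g1"))
  expect_false("F1" %in% g1$family_id)
  expect_equal(nrow(g1), 4)
  # coordinates of downstream genes shift left by the removed span
  expect_equal(g1$start[1], 200L)

  # duplication then loss of the same gene restores the copy number
  g2 <- apply_event(g, list(event_type = "duplication", family_id = "F2",
                            source_gene_id = "g2", gene_id = "new",
                            insert_at = 3L))
  expect_equal(sum(g2$family_id == "F2"), 3)
  g3 <- apply_event(g2, list(event_type = "loss", family_id = "F2",
                             gene_id = "new"))
  expect_equal(sum(g3$family_id == "F2"), 2)
  expect_equal(as.data.frame(g3), as.data.frame(g))

  # lgt carries its donor label; translocation conserves copy number
  g4 <- apply_event(g, list(event_type = "lgt", family_id = "LX",
                            gene_id = "lg", len = 600L, strand = "+",
                            donor_taxon = "Bacteria:Firmicutes",
                            insert_at = 1L))
  expect_equal(g4$family_id[1], "LX")
  expect_equal(g4$donor_taxon[1], "Bacteria:Firmicutes")
  g5 <- apply_event(g, list(event_type = "translocation", family_id = "F1",
                            gene_id = "g1", insert_at = 5L))
  expect_equal(sort(g5$family_id), sort(g$family_id))
  expect_equal(g5$family_id[5], "F1")

  # inapplicable events error rather than silently no-op
  expect_error(apply_event(g, list(event_type = "loss", family_id = "ZZ")),
               class = "gvaccordion_inapplicable_event_error")
  expect_error(apply_event(g1, list(event_type = "excision",
                                    family_id = "F1")),
               class = "gvaccordion_inapplicable_event_error")
})

test_that("random event sequences replay exactly and balance the books", {
  set.seed(42)
  tree <- ape::read.tree(text = "(A:2,B:2);")
  cfg <- accordion_config(
    rates = c(duplication = 12, loss = 12, lgt = 6, mge_insertion = 5,
              mge_excision = 5, translocation = 6, orphan_genesis = 5),
    initial_gene_count = 60, paralog_family_count = 5, mge_family_count = 3,
    seed = 99)
  sim <- simulate_accordion(cfg, tree)
  expect_gt(nrow(sim$events), 50) # a long, mixed event sequence

  for (tip in names(sim$genomes)) {
    replayed <- replay_events(sim$root_genome, sim$events,
                              path_to_tip(sim$tree, tip),
                              gap = cfg$intergenic_len)
    expect_equal(as.data.frame(replayed), as.data.frame(sim$genomes[[tip]]))
    ev <- dplyr::filter(sim$events, branch == tip)
    gains <- sum(ev$event_type %in% c("duplication", "lgt", "insertion",
                                      "orphan"))
    losses <- sum(ev$event_type %in% c("loss", "excision"))
    expect_equal(nrow(sim$genomes[[tip]]),
                 nrow(sim$root_genome) + gains - losses)
  }
})

test_that("simulation is deterministic under a fixed seed and varies across seeds", {
  tree <- balanced6()
  cfg <- accordion_preset("chlorella_like", seed = 7)
  s1 <- simulate_accordion(cfg, tree)
  s2 <- simulate_accordion(cfg, tree)
  expect_identical(s1$events, s2$events)
  expect_identical(lapply(s1$genomes, as.data.frame),
                   lapply(s2$genomes, as.data.frame))
  expect_identical(unclass(s1$markers), unclass(s2$markers))
  s3 <- simulate_accordion(accordion_preset("chlorella_like", seed = 8), tree)
  expect_false(identical(s1$events, s3$events))
})

test_that("all-zero rates leave every tip identical to the root", {
  tree <- balanced6()
  cfg <- accordion_config(rates = c(duplication = 0), marker_sub_rate = 0,
                          initial_gene_count = 40, paralog_family_count = 2,
                          mge_family_count = 1, seed = 3)
  sim <- simulate_accordion(cfg, tree)
  expect_equal(nrow(sim$events), 0)
  for (tip in names(sim$genomes)) {
    expect_equal(as_genes_df(sim$genomes[[tip]]),
                 as_genes_df(sim$root_genome))
    expect_equal(percent_identity(unclass(sim$markers)[[tip]],
                                  sim$root_markers), 100)
  }
})

test_that("equal birth and death rates keep the expected gene count at its start", {
  # tip gene count is a martingale when duplication and loss rates match
  tree <- ape::read.tree(text = "(A:1,B:1);")
  set.seed(5)
  n0 <- 40L
  counts <- vapply(1:120, function(i) {
    cfg <- accordion_config(rates = c(duplication = 3, loss = 3),
                            initial_gene_count = n0,
                            paralog_family_count = 3, mge_family_count = 0,
                            seed = 1000L + i)
    sim <- simulate_accordion(cfg, tree)
    nrow(sim$genomes$A)
  }, numeric(1))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - n0), 4 * se + 1e-9)
})

test_that("marker divergence follows the Jukes-Cantor decay", {
  t <- 1.5; mu <- 0.3
  tree <- ape::read.tree(text = sprintf("(A:%f,B:%f);", t, t))
  expected <- 100 * (0.25 + 0.75 * exp(-4 * mu * t / 3))
  set.seed(21)
  ids <- vapply(1:10, function(i) {
    cfg <- accordion_config(rates = c(duplication = 0), marker_sub_rate = mu,
                            initial_gene_count = 10,
                            paralog_family_count = 0, mge_family_count = 0,
                            seed = 2000L + i)
    sim <- simulate_accordion(cfg, tree)
    percent_identity(unclass(sim$markers)[["A"]], sim$root_markers)
  }, numeric(1))
  se <- stats::sd(ids) / sqrt(length(ids))
  expect_lt(abs(mean(ids) - expected), 4 * se)
})

test_that("group presets encode the published gain/loss signatures", {
  ostreo <- accordion_preset("ostreococcus_like")
  expect_equal(unname(ostreo$rates[c("mge_insertion", "mge_excision")]),
               c(0, 0))
  expect_gt(ostreo$rates["lgt"], ostreo$rates["duplication"])

  micro <- accordion_preset("micromonas_like")
  expect_equal(unname(micro$rates[c("mge_insertion", "mge_excision")]),
               c(0, 0))
  expect_gt(micro$rates["lgt"], micro$rates["duplication"])

  chlorella <- accordion_preset("chlorella_like")
  expect_gt(chlorella$rates["mge_insertion"], 0)
  expect_gt(chlorella$rates["mge_excision"], 0)

  for (g in c("mimivirus_like", "megavirus_like")) {
    p <- accordion_preset(g)
    expect_gt(p$rates["duplication"] + p$rates["loss"],
              sum(p$rates) - (p$rates["duplication"] + p$rates["loss"]))
    expect_gte(p$positional_bias, 0.5)
  }

  expect_error(accordion_preset("unknown"),
               class = "gvaccordion_value_error")
})
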