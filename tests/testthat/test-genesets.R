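meta_for <- function(id) {
  comparison_meta("trt", "ctl", "mouse", "musc", sprintf("GSE%d", id), id)
}

test_that("extraction caps at 300 genes ranked by B", {
  de <- generate_de_table(500, 450, 0, seed = 1)
  pair <- extract_gene_sets(de, meta_for(1))
  expect_length(pair$up$genes, 300)
  expect_length(pair$down$genes, 0)
  # the kept genes are exactly the 300 highest-B significant genes
  sig <- de[de$adj.P.Val < 0.05, ]
  top <- sig$gene[order(-sig$B, sig$P.Value, sig$gene)][1:300]
  expect_setequal(pair$up$genes, top)
})

test_that("below the cap, both directions are split exactly", {
  de <- generate_de_table(200, 10, 5, seed = 2)
  pair <- extract_gene_sets(de, meta_for(2))
  expect_length(pair$up$genes, 10)
  expect_length(pair$down$genes, 5)
  expect_length(intersect(pair$up$genes, pair$down$genes), 0)
  sig <- de[de$adj.P.Val < 0.05, ]
  expect_setequal(pair$up$genes, sig$gene[sig$logFC > 0])
  expect_setequal(pair$down$genes, sig$gene[sig$logFC < 0])
})

test_that("comparisons without significant genes yield two empty, named sets", {
  de <- generate_de_table(100, 0, 0, seed = 3)
  pair <- extract_gene_sets(de, meta_for(3))
  expect_length(pair$up$genes, 0)
  expect_length(pair$down$genes, 0)
  expect_identical(pair$up$name, "up_in_trt_v_ctl___mouse_musc_3")
  expect_identical(pair$down$name, "down_in_trt_v_ctl___mouse_musc_3")
})

test_that("significant genes with exactly zero fold change join neither set", {
  de <- generate_de_table(50, 5, 0, seed = 4)
  de$logFC[de$adj.P.Val < 0.05][1] <- 0
  expect_message(pair <- extract_gene_sets(de, meta_for(4)), "zero")
  expect_length(pair$up$genes, 4)
})

test_that("collections hold exactly two sets per comparison in input order", {
  comparisons <- lapply(1:3, function(i) {
    list(de = generate_de_table(100, if (i == 2) 0 else 8,
                                if (i == 2) 0 else 4, seed = i),
         meta = meta_for(i))
  })
  col <- build_collection(comparisons)
  expect_length(col, 6L)
  expect_equal(sum(vapply(col, length, integer(1)) == 0L), 2L)
  expect_match(names(col)[1], "^up_in")
  expect_match(names(col)[2], "^down_in")
  comparisons[[2]]$meta <- meta_for(1)
  expect_error(build_collection(comparisons), "duplicate")
})

test_that("an eligible comparison yields exactly nine nested consensus sets", {
  set.seed(5)
  pool <- sprintf("GENE%02d", 1:40)
  studies <- lapply(1:4, function(i) {
    study_pair(sample(pool[1:20], 12), sample(pool[21:40], 12), i)
  })
  out <- consensus_build(studies, "MurineSkelMusc_Trt_v_Ctl")
  expect_length(out, 9L)
  cats <- vapply(out, function(s) s$category, character(1))
  expect_equal(sort(unique(cats)), c("down", "same", "up"))
  # nesting within each category
  for (cat in c("up", "down", "same")) {
    g30 <- out[[consensus_name("MurineSkelMusc_Trt_v_Ctl", cat, 0.3)]]$genes
    g50 <- out[[consensus_name("MurineSkelMusc_Trt_v_Ctl", cat, 0.5)]]$genes
    g70 <- out[[consensus_name("MurineSkelMusc_Trt_v_Ctl", cat, 0.7)]]$genes
    expect_true(all(g70 %in% g50))
    expect_true(all(g50 %in% g30))
    # up and down are subsets of same at each threshold
    if (cat != "same") {
      same <- out[[consensus_name("MurineSkelMusc_Trt_v_Ctl", "same",
                                  0.3)]]$genes
      expect_true(all(g30 %in% same))
    }
  }
})

test_that("support is counted over studies with exact threshold arithmetic", {
  # gene in 2 of 5 studies' up sets: 2/5 = 0.4 -> in the 30% set, not 50%
  studies <- lapply(1:5, function(i) {
    study_pair(if (i <= 2) c("SHARED", sprintf("U%d", i)) else
                 sprintf("U%d", i),
               sprintf("D%d", i), i)
  })
  out <- consensus_build(studies, "Tag_A_v_B",
                         consensus_config(min_sets_per_comparison = 8,
                                          min_sets_per_direction = 4))
  expect_true("SHARED" %in% out[["Tag_A_v_B__up30"]]$genes)
  expect_false("SHARED" %in% out[["Tag_A_v_B__up50"]]$genes)
  # exact boundaries: 3/10 meets 30%, 7/10 meets 70%
  studies10 <- lapply(1:10, function(i) {
    study_pair(c(if (i <= 3) "AT30", if (i <= 7) "AT70",
                 sprintf("U%d", i)), sprintf("D%d", i), i)
  })
  out10 <- consensus_build(studies10, "Tag_A_v_B")
  expect_true("AT30" %in% out10[["Tag_A_v_B__up30"]]$genes)
  expect_false("AT30" %in% out10[["Tag_A_v_B__up50"]]$genes)
  expect_true("AT70" %in% out10[["Tag_A_v_B__up70"]]$genes)
})

test_that("a gene present in every up set reaches all up and same sets", {
  studies <- lapply(1:4, function(i) {
    study_pair(c("EVERY", sprintf("U%d", i)), sprintf("D%d", i), i)
  })
  out <- consensus_build(studies, "Tag_A_v_B")
  for (tau in c(0.3, 0.5, 0.7)) {
    expect_true("EVERY" %in% out[[consensus_name("Tag_A_v_B", "up",
                                                 tau)]]$genes)
    expect_true("EVERY" %in% out[[consensus_name("Tag_A_v_B", "same",
                                                 tau)]]$genes)
  }
})

test_that("strict consistency excludes genes with any opposing evidence", {
  studies <- lapply(1:4, function(i) {
    study_pair(c("MIXED", sprintf("U%d", i)),
               c(if (i == 4) "MIXED", sprintf("D%d", i)), i)
  })
  strict <- consensus_build(studies, "Tag_A_v_B")
  expect_false(any(vapply(strict, function(s) "MIXED" %in% s$genes,
                          logical(1))))
  relaxed <- consensus_build(studies, "Tag_A_v_B", strict = FALSE)
  expect_true("MIXED" %in% relaxed[["Tag_A_v_B__up30"]]$genes)
  expect_true("MIXED" %in% relaxed[["Tag_A_v_B__same30"]]$genes)
})

test_that("ineligible comparisons are skipped with the reason logged", {
  studies3 <- lapply(1:3, function(i) {
    study_pair(sprintf("U%d", i), sprintf("D%d", i), i)
  })
  expect_message(out <- consensus_build(studies3, "Tag_A_v_B"), "skipped")
  expect_length(out, 0L)
  # 8 sets but imbalanced 6 up / 2 down fails the per-direction floor
  studies_imb <- c(
    lapply(1:2, function(i) study_pair(sprintf("U%d", i),
                                       sprintf("D%d", i), i)),
    lapply(3:6, function(i) {
      s <- study_pair(sprintf("U%d", i), sprintf("D%d", i), i)
      s$down <- NULL
      s
    }))
  expect_message(out2 <- consensus_build(studies_imb, "Tag_A_v_B"),
                 "skipped")
  expect_length(out2, 0L)
})

test_that("consensus matches the brute-force counting oracle on random collections", {
  set.seed(6)
  pool <- sprintf("GENE%02d", 1:50)
  for (rep in 1:8) {
    n_studies <- sample(4:10, 1)
    studies <- lapply(seq_len(n_studies), function(i) {
      study_pair(sample(pool, sample(0:12, 1)),
                 sample(pool, sample(0:12, 1)), i)
    })
    out <- consensus_build(studies, "Tag_A_v_B")
    oracle <- brute_consensus(studies, "Tag_A_v_B")
    expect_length(out, 9L)
    for (nm in names(oracle)) {
      expect_setequal(out[[nm]]$genes, oracle[[nm]])
    }
  }
})

test_that("consensus sets write to GMT with their provenance info", {
  studies <- lapply(1:4, function(i) {
    study_pair(c("A", sprintf("U%d", i)), sprintf("D%d", i), i)
  })
  out <- consensus_build(studies, "Tag_A_v_B")
  col <- gene_set_collection(unname(out))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(col, path)
  back <- read_gmt(path)
  expect_length(back, 9L)
  expect_match(back[["Tag_A_v_B__up30"]]$info, "k=4")
})
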