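# Reaction strings, tokenizer, vocabulary, bins, groups, splits, table I/O.

test_that("canonicalization maps equivalent SMILES to one anchor form", {
  expect_identical(canonicalize_reaction("OCC>>CCO"), "CCO>>CCO")
  # fragment order within a segment never matters
  expect_identical(canonicalize_reaction("C1CC1.CCO>>CCO"),
                   canonicalize_reaction("CCO.C1CC1>>CCO"))
  # idempotence on already-canonical input
  x <- canonicalize_reaction("c1ccccc1Br.OCC>[Pd].CS(C)=O>c1ccccc1CCO")
  expect_identical(canonicalize_reaction(x), x)
})

test_that("canonicalization is idempotent across a generated corpus", {
  smi <- fx_corpus()$records$reaction_smiles
  once <- canonicalize_reaction(smi)
  expect_identical(canonicalize_reaction(once), once)
})

test_that("reaction parsing validates separators and segments", {
  expect_error(canonicalize_reaction("CCO>CCO"), class = "rxy_parse_error")
  expect_error(canonicalize_reaction("CCO>>CC>O"), class = "rxy_parse_error")
  expect_error(canonicalize_reaction(">>CCO"), class = "rxy_parse_error")
  # an unparseable fragment is reported with its segment
  err <- tryCatch(canonicalize_reaction("C(C>O>CCO"), rxy_parse_error = identity)
  expect_match(conditionMessage(err), "reactant segment")
})

test_that("tokenizer follows the SMILES regex rules and is lossless", {
  expect_identical(tokenize_reaction("CCO"), c("C", "C", "O"))
  expect_identical(tokenize_reaction("ClC(Cl)=O"),
                   c("Cl", "C", "(", "Cl", ")", "=", "O"))
  expect_identical(tokenize_reaction("[Pd]"), "[Pd]")
  expect_identical(tokenize_reaction("C%12CC%12"), c("C", "%12", "C", "C", "%12"))
  expect_identical(tokenize_reaction("CC>O>CO"),
                   c("C", "C", ">", "O", ">", "C", "O"))
  for (s in fx_corpus()$records$reaction_smiles) {
    expect_identical(paste(tokenize_reaction(s), collapse = ""), s)
  }
})

test_that("tokenizer reports unknown characters with their offset", {
  err <- tryCatch(tokenize_reaction("CCXO"), rxy_tokenize_error = identity)
  expect_match(conditionMessage(err), "'X' at offset 3")
})

test_that("vocabulary is deterministic, complete, and maps unknowns to [UNK]", {
  v <- build_vocabulary("CCO>>CCO")
  expect_length(v$tokens, 8L)  # C, O, > plus 5 reserved
  expect_setequal(setdiff(v$tokens, c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")),
                  c("C", "O", ">"))
  expect_identical(v, build_vocabulary("CCO>>CCO"))
  expect_identical(token_ids("N", v), v$unk)
  expect_error(build_vocabulary(character(0)), class = "rxy_empty_corpus_error")
  # observed tokens ordered by frequency, ties broken lexicographically:
  # ">" and "C" both occur 4 times, "N" and "O" twice
  v2 <- build_vocabulary(c("CCO>>CCO", "N>>N"))
  expect_identical(v2$tokens[-(1:5)], c(">", "C", "N", "O"))
})

test_that("yield bins follow the declared boundary convention", {
  lv <- c("extremely_low", "low", "medium", "high")
  got <- bin_yield(c(0, 29.999, 30, 49.999, 50, 79.999, 80, 85, 100))
  expect_identical(as.character(got),
                   lv[c(1, 1, 2, 2, 3, 3, 4, 4, 4)])
  expect_error(bin_yield(-1), class = "rxy_range_error")
  expect_error(bin_yield(100.5), class = "rxy_range_error")
})

test_that("reaction groups partition records by reactants and products only", {
  r <- reaction_records(
    c("CCO>[Pd]>CCN", "CCO>O>CCN", "CCO>O>CCC", "CC>>CC"),
    c(90, 40, 10, 55))
  g <- build_reaction_groups(r)
  expect_identical(g$records$group_id, c("G00001", "G00001", "G00002", "G00003"))
  expect_identical(g$groups$size, c(2L, 1L, 1L))
  # every record lands in exactly one group
  expect_identical(sum(g$groups$size), nrow(r))
})

test_that("group-stratified split apportions members within groups", {
  one_group <- reaction_records(rep("CC>O>CC", 10), seq(5, 95, 10))
  sp <- stratified_split(one_group, c(8, 1, 1), seed = 4)
  expect_identical(vapply(sp, nrow, 1L), c(train = 8L, val = 1L, test = 1L))

  single <- reaction_records("CC>O>CC", 50)
  sp1 <- stratified_split(single, c(8, 1, 1), seed = 4)
  expect_identical(nrow(sp1$train), 1L)

  records <- fx_corpus()$records
  sp2 <- stratified_split(records, c(6, 2, 2), seed = 11)
  expect_identical(sum(vapply(sp2, nrow, 1L)), nrow(records))
  # deterministic
  sp3 <- stratified_split(records, c(6, 2, 2), seed = 11)
  expect_identical(sp2, sp3)
  expect_error(stratified_split(records, c(1, 1), seed = 1),
               class = "rxy_config_error")
})

test_that("per-group split counts deviate from exact ratios by at most one", {
  records <- fx_corpus()$records
  sp <- stratified_split(records, c(6, 2, 2), seed = 11)
  keys <- rxnyield:::group_key(records$reaction_smiles)
  for (k in unique(keys)) {
    n <- sum(keys == k)
    if (n < 3) next
    got <- vapply(sp, function(part)
      sum(rxnyield:::group_key(part$reaction_smiles) == k), 1L)
    expect_true(all(abs(got - n * c(0.6, 0.2, 0.2)) <= 1))
  }
})

test_that("group-size filtering applies a strict training-set threshold", {
  train <- reaction_records(
    c(rep("CC>O>CC", 6), rep("CN>O>CN", 3)), rep(50, 9))
  test <- reaction_records(
    c("CC>[Pd]>CC", "CN>[Pd]>CN", "CO>[Pd]>CO"), rep(60, 3))
  expect_identical(filter_test_by_group_size(test, train, 5)$reaction_smiles,
                   "CC>[Pd]>CC")
  expect_identical(nrow(filter_test_by_group_size(test, train, 0)), 2L)
  expect_identical(nrow(filter_test_by_group_size(test, train, 100)), 0L)
})

test_that("reaction tables round-trip through CSV", {
  records <- reaction_records(
    c("CCO>[Pd]>CCN", "CC>>CC"), c(91.25, 3),
    group_id = c("G00001", NA), category_id = c(4L, NA))
  p <- withr::local_tempfile(fileext = ".csv")
  write_reaction_table(records, p)
  expect_identical(read_reaction_table(p), records)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("reaction_smiles,yield", "CC>>CC,105"), bad)
  expect_error(read_reaction_table(bad), class = "rxy_range_error")
  writeLines(c("reaction_smiles,pct", "CC>>CC,50"), bad)
  expect_error(read_reaction_table(bad), class = "rxy_schema_error")
  writeLines(c("reaction_smiles,yield", "CC>>CC,x5"), bad)
  expect_error(read_reaction_table(bad), class = "rxy_parse_error")
})
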