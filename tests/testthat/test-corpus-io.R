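test_that("read_pubmed_csv reads PubMed exports and reports dropped rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(PMID = c("1", "2", "3"),
                       Title = c("a", "b", "c"),
                       Abstract = c("x", "y", "z")), f, row.names = FALSE)
  rec <- read_pubmed_csv(f)
  expect_equal(nrow(rec), 3)
  expect_equal(attr(rec, "load_report")$dropped_missing_pmid, 0)

  write.csv(data.frame(PMID = c("1", "", "3"),
                       Title = "t", Abstract = "a"), f, row.names = FALSE)
  rec <- read_pubmed_csv(f)
  expect_equal(nrow(rec), 2)
  expect_equal(attr(rec, "load_report")$dropped_missing_pmid, 1)

  ## column remapping
  write.csv(data.frame(id = "7", text = "abs"), f, row.names = FALSE)
  rec <- read_pubmed_csv(f, column_map = c(pmid = "id", abstract = "text"))
  expect_equal(rec$pmid, "7")
  expect_equal(rec$abstract, "abs")

  expect_error(read_pubmed_csv(f), class = "crmlit_format_error")
  expect_error(read_pubmed_csv(tempfile()), class = "crmlit_io_error")
})

test_that("generated abstract CSV round-trips through the reader", {
  corpus <- generate_corpus(corpus_config(n_articles = 50, seed = 1),
                            dir = withr::local_tempdir())
  rec <- read_pubmed_csv(corpus$paths$abstracts)
  expect_equal(nrow(rec), 50)
  expect_identical(rec$pmid, corpus$truth$articles$pmid)
  ## write back and re-read: identical records
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(PMID = rec$pmid, Title = rec$title,
                       Abstract = rec$abstract, Year = rec$year),
            f2, row.names = FALSE)
  rec2 <- read_pubmed_csv(f2)
  expect_identical(rec2$abstract, rec$abstract)
  expect_identical(rec2$pmid, rec$pmid)
})

test_that("keyword_prefilter matches whole words case-insensitively", {
  rec <- make_records(1:3,
                      title = c("Drosophila enhancer study", "butterfly wings", "other"),
                      abstract = c("", "nothing here", "the fly genome"))
  kept <- keyword_prefilter(rec, c("Drosophila", "fly"))
  expect_identical(kept$pmid, c("1", "3"))
  expect_error(keyword_prefilter(rec, character()), class = "crmlit_config_error")

  ## generator-style bookkeeping: plant keyword in a known subset
  set.seed(3)
  has_kw <- sample(c(rep(TRUE, 40), rep(FALSE, 60)))
  rec <- make_records(1:100, title = "t",
                      abstract = ifelse(has_kw, "a fly abstract", "plain abstract"))
  expect_equal(nrow(keyword_prefilter(rec, "fly")), 40)
})

test_that("parse_jats maps paragraphs to their innermost section", {
  doc <- jats_doc(list(list(title = "Results", paragraphs = c("p1", "p2"))))
  ft <- parse_jats(doc)
  expect_length(ft$sections, 1)
  expect_identical(ft$sections[[1]]$title, "Results")
  expect_identical(ft$sections[[1]]$paragraphs, c("p1", "p2"))

  nested <- paste0("<article><body><sec><title>Outer</title><p>po</p>",
                   "<sec><title>Inner</title><p>pi</p></sec></sec></body></article>")
  ft <- parse_jats(nested)
  titles <- vapply(ft$sections, `[[`, "", "title")
  expect_identical(titles, c("Outer", "Inner"))
  expect_identical(ft$sections[[2]]$paragraphs, "pi")

  expect_error(parse_jats("<article><front/></article>"),
               class = "crmlit_format_error")
  expect_error(parse_jats("<article><body><p>x"), class = "crmlit_parse_error")
})

test_that("generated JATS round-trips its section and paragraph structure", {
  corpus <- generate_corpus(corpus_config(n_articles = 30, positive_fraction = 0.2,
                                          seed = 2),
                            dir = withr::local_tempdir())
  pm <- corpus$truth$articles$pmid[corpus$truth$articles$is_crm][1]
  ft <- fetch_fulltext(pm, local_dir_transport(corpus$paths$fulltext_dir))
  titles <- vapply(ft$sections, `[[`, "", "title")
  expect_identical(titles, c("Introduction", "Results", "Discussion",
                             "Materials and Methods", "Acknowledgements"))
  n_res <- sum(corpus$truth$mentions$pmid == pm & !corpus$truth$mentions$decoy)
  expect_length(ft$sections[[2]]$paragraphs, n_res)
})

test_that("fetch_fulltext distinguishes unavailable, malformed, and failed", {
  tp <- list_transport(list(x1 = jats_doc(list(list(title = "R", paragraphs = "p")))))
  ft <- fetch_fulltext("x1", tp)
  expect_s3_class(ft, "article_fulltext")
  expect_identical(ft$pmid, "x1")

  expect_null(fetch_fulltext("absent", tp))

  bad <- list_transport(list(x2 = "<article><body><p>oops"))
  expect_error(fetch_fulltext("x2", bad), class = "crmlit_parse_error")

  failing <- structure(list(get = function(pmid) stop("socket timeout")),
                       class = "fulltext_transport")
  expect_error(fetch_fulltext("x3", failing), class = "crmlit_retrieval_error")
})

test_that("filter_sections drops the default non-result sections", {
  ft <- parse_jats(jats_doc(list(
    list(title = "Results", paragraphs = c("r1", "r2")),
    list(title = "Materials and Methods", paragraphs = "m1"),
    list(title = "ACKNOWLEDGEMENTS", paragraphs = "a1"),
    list(title = "References", paragraphs = "ref"))))
  ft$pmid <- "p"
  out <- filter_sections(ft)
  expect_identical(out$text, c("r1", "r2"))
  expect_identical(out$index, 0:1)

  all_out <- filter_sections(ft, removal_titles = character())
  expect_identical(all_out$text, c("r1", "r2", "m1", "a1", "ref"))
})

test_that("write_outputs writes per-step CSVs with an accurate manifest", {
  d <- withr::local_tempdir()
  man <- write_outputs(list(), d)
  expect_identical(man$rows, c(0L, 0L, 0L))
  for (p in man$path) expect_true(file.exists(p))

  step4 <- data.frame(pmid = "1", gene = c("a", "b"), target_gene = TRUE,
                      regulatory_tf = FALSE, max_target_prob = 0.9,
                      max_tf_prob = 0.1, supporting_target = "0",
                      supporting_tf = "")
  step3 <- data.frame(pmid = "1", gene = "a", paragraph_index = 0L,
                      section = "Results",
                      target_gene_prob = 0.123456789, tf_prob = 0.987654321,
                      target_gene = FALSE, regulatory_tf = TRUE, text = "w")
  man <- write_outputs(list(step3 = step3, step4 = step4), d)
  expect_equal(man$rows[man$file == "step4_summary.csv"], 2L)
  back <- read.csv(file.path(d, "step3_pairs.csv"))
  expect_equal(back$target_gene_prob, 0.123456789, tolerance = 1e-7)
  expect_equal(back$tf_prob, 0.987654321, tolerance = 1e-7)
})
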