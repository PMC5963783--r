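test_that("database building filters by AluI site count with a strict > rule", {
  many <- list(id = "rep501", gene_label = "R",
               seq = paste(rep("AGCT", 501), collapse = ""))
  # 4-periodic AGCT repeats: n copies give n sites
  just <- list(id = "rep500", gene_label = "R2",
               seq = paste(rep("AGCT", 500), collapse = ""))
  plain <- make_sited_transcript(2, id = "ok", gene = "OK")
  tx <- do.call(rbind, lapply(list(many, just, plain), as.data.frame))
  tx$length <- nchar(tx$seq)
  db <- build_db(tx, lego_config())
  expect_setequal(db$transcripts$id, c("rep500", "ok"))

  expect_error(build_db(tx[1, ], lego_config()), "empty database")
})

test_that("tags map to their source site and scrambled tags do not map", {
  set.seed(31)
  tx <- data.frame(id = c("t1", "t2"), gene_label = c("G1", "G2"),
                   seq = c(random_dna(800), random_dna(800)),
                   stringsAsFactors = FALSE)
  db <- build_db(tx, lego_config())
  v <- enumerate_vectors(tx[1, ], lego_config())
  v <- v[v$realizable, ]
  res <- map_tags(v$guide[1], db)
  expect_equal(unique(res$hits$transcript_id), "t1")
  expect_equal(res$hits$site_index[1], v$site_index[1])

  scrambled <- paste(rev(strsplit(v$guide[1], "")[[1]]), collapse = "")
  res2 <- map_tags(scrambled, db)
  expect_equal(nrow(res2$hits), 0L)
  expect_equal(res2$unmapped, scrambled)
})

test_that("a tag hitting duplicated transcripts retains both hits", {
  tr <- make_sited_transcript(2, id = "a", gene = "GA")
  tx <- data.frame(id = c("a", "a_copy"), gene_label = c("GA", "GA"),
                   seq = c(tr$seq, tr$seq), stringsAsFactors = FALSE)
  db <- build_db(tx, lego_config())
  v <- enumerate_vectors(tx[1, ], lego_config())
  v <- v[v$realizable, ]
  res <- map_tags(v$guide[1], db)
  expect_setequal(res$hits$transcript_id, c("a", "a_copy"))
})

test_that("clustering links by identity and single-sided coverage", {
  set.seed(41)
  base <- random_dna(1000)
  mutate_n <- function(seq, n) {
    pos <- sample(50:950, n)  # keep the ends intact
    for (p in pos) {
      seq <- mutate_at(seq, p, sample(setdiff(c("A", "C", "G", "T"),
                                              substr(seq, p, p)), 1))
    }
    seq
  }
  tx <- data.frame(
    id = c("orig", "copy", "sub95", "sub94", "unrelated"),
    gene_label = c("G1", "G1", "G1", "G1", "G2"),
    seq = c(base, base, mutate_n(base, 50), mutate_n(base, 60),
            random_dna(1000)),
    stringsAsFactors = FALSE)
  tx$length <- nchar(tx$seq)

  cl_all <- cluster_transcripts(tx, lego_config())
  in_cluster <- function(cl, a, b) {
    any(vapply(strsplit(cl$members, ","), function(m) all(c(a, b) %in% m),
               logical(1)))
  }
  expect_true(in_cluster(cl_all, "orig", "copy"))       # exact duplicate
  expect_true(in_cluster(cl_all, "orig", "sub95"))      # 95% identity
  expect_false(in_cluster(cl_all, "orig", "sub94"))     # 94% identity
  expect_false(in_cluster(cl_all, "orig", "unrelated"))

  # permutation invariance of membership
  perm <- tx[c(3, 5, 1, 4, 2), ]
  cl_perm <- cluster_transcripts(perm, lego_config())
  expect_setequal(cl_all$members, cl_perm$members)
})

test_that("minimal set cover is exact with the documented tie-breaks", {
  expect_equal(minimal_cluster_set(list(A = c("a", "b"), B = "a"),
                                   c("a", "b")), "A")
  # size-2 cover beats size-3; {A,B} explains 4 tag slots vs {A,C} covering
  # fails (b missing from C)
  sel <- minimal_cluster_set(list(A = c("a", "b"), B = c("b", "c"), C = "c"),
                             c("a", "b", "c"))
  expect_equal(sel, c("A", "B"))
  expect_error(minimal_cluster_set(list(A = "a"), c("a", "zz")),
               "not explained")
})

test_that("set cover matches brute force on random instances", {
  set.seed(51)
  brute_min_size <- function(masks, m) {
    n <- length(masks)
    bits <- vapply(masks, function(x) sum(2^(x - 1L)), numeric(1))
    full <- 2^m - 1
    best <- n
    for (s in seq_len(2^n - 1)) {
      sel <- which(bitwAnd(s, 2^(seq_len(n) - 1L)) > 0)
      if (length(sel) >= best) next
      if (sum(2^(unique(unlist(masks[sel])) - 1L)) == full) {
        best <- length(sel)
      }
    }
    best
  }
  for (rep in 1:60) {
    n <- sample(3:9, 1)
    m <- sample(3:8, 1)
    masks <- lapply(seq_len(n), function(i) {
      sort(sample(seq_len(m), sample(1:m, 1)))
    })
    # guarantee coverability
    masks[[1]] <- sort(unique(c(masks[[1]], seq_len(m))))
    names(masks) <- paste0("c", seq_len(n))
    tags <- as.character(seq_len(m))
    masks_chr <- lapply(masks, as.character)
    sel <- minimal_cluster_set(masks_chr, tags)
    expect_equal(length(sel), brute_min_size(masks, m))
  }
})

test_that("greedy fallback engages above the exact-enumeration limit", {
  cl <- lapply(1:30, function(i) as.character(i))
  names(cl) <- sprintf("c%02d", 1:30)
  cl$all <- as.character(1:30)
  expect_warning(sel <- minimal_cluster_set(cl, as.character(1:30)),
                 "greedy")
  expect_equal(sel, "all")
})

test_that("AluI-coverage filtering applies the strict >15% rule and ambiguity", {
  cl <- data.frame(
    cluster_id = c("c1", "c2", "c3", "c4"),
    representative = c("r1", "r2", "r3", "r4"),
    members = c("r1", "r2", "r3,r3b", "r4"),
    gene_labels = c("gA", "gB", "geneX,geneY", "gD"),
    n_members = c(1L, 1L, 2L, 1L),
    alui_sites = c(9L, 9L, 5L, 0L),
    max_possible_vectors = c(18L, 18L, 10L, 0L),
    ambiguous = c(FALSE, FALSE, TRUE, FALSE),
    n_tags = c(3L, 2L, 5L, 1L),
    stringsAsFactors = FALSE)
  expect_warning(out <- filter_alui_coverage(cl, lego_config()), "AluI")
  expect_equal(out$status,
               c("selected", "low_coverage", "ambiguous", "no_alui_sites"))
  expect_equal(out$coverage[1], 3 / 18)   # 16.7% > 15%
  expect_equal(out$coverage[2], 2 / 18)   # 11.1% removed
})
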