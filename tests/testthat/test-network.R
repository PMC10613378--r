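write_billing_file <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("read_billing validates schema, dates and windows", {
  df <- data.frame(physician_id = c("p1", "p2", "p1"),
                   patient_id = c("t1", "t1", "t2"),
                   hospital_id = "h1",
                   date = c("2019-03-01", "2019-04-01", "2020-02-01"))
  path <- write_billing_file(df)
  suppressMessages({
    all_rows <- read_billing(path)
    windowed <- read_billing(path, window = c("2019-01-01", "2019-12-31"))
  })
  expect_equal(nrow(all_rows), 3)
  expect_s3_class(all_rows$date, "Date")
  expect_equal(nrow(windowed), 2)

  empty <- write_billing_file(df[0, ])
  suppressMessages(expect_equal(nrow(read_billing(empty)), 0))

  noh <- write_billing_file(df[setdiff(names(df), "hospital_id")])
  expect_error(suppressMessages(read_billing(noh)), "hospital_id")

  bad <- df; bad$date[2] <- "not-a-date"
  expect_error(suppressMessages(read_billing(write_billing_file(bad))),
               "line 3")
})

test_that("encounter matrix tallies rows per physician-patient pair", {
  recs <- data.frame(physician_id = c("a", "b"), patient_id = "t1",
                     hospital_id = "h1", date = as.Date("2019-01-01"))
  Z <- build_encounter_matrix(recs)
  expect_equal(as.matrix(Z$counts),
               matrix(c(1, 1), 2, 1, dimnames = list(c("a", "b"), "t1")))

  recs3 <- recs[c(1, 1, 1), ]
  expect_equal(as.numeric(build_encounter_matrix(recs3)$counts["a", "t1"]), 3)

  expect_warning(Ze <- build_encounter_matrix(recs[0, ]), "empty")
  expect_true(Ze$empty)

  set.seed(4)
  z <- random_counts(4, 5)
  rr <- records_from_counts(z)
  Zr <- build_encounter_matrix(rr)
  expect_equal(sum(Zr$counts), nrow(rr))
  tally <- table(factor(rr$patient_id, levels = Zr$patients))
  expect_equal(as.numeric(Matrix::colSums(Zr$counts)), as.numeric(tally))
})

test_that("projection matches its definitions and the brute-force oracle", {
  z <- matrix(c(1, 1, 0,
                1, 1, 0,
                0, 0, 2), 3, 3, byrow = TRUE,
              dimnames = list(c("i", "j", "k"), c("t1", "t2", "t3")))
  Z <- build_encounter_matrix(records_from_counts(z))
  A <- project_shared_patients(Z, "shared-count")
  expect_equal(as.numeric(A$weights["i", "j"]), 2)
  expect_equal(sum(A$weights["k", ]), 0)  # isolated physician

  zg <- matrix(c(4, 9), 2, 1, dimnames = list(c("i", "j"), "t1"))
  Ag <- project_shared_patients(build_encounter_matrix(records_from_counts(zg)),
                                "geometric-mean")
  expect_equal(as.numeric(Ag$weights["i", "j"]), 6)

  set.seed(8)
  for (r in 1:5) {
    z <- random_counts(sample(3:7, 1), sample(4:9, 1))
    Z <- build_encounter_matrix(records_from_counts(z))
    z <- z[Z$physicians, Z$patients, drop = FALSE]
    for (scheme in c("shared-count", "geometric-mean")) {
      got <- as.matrix(project_shared_patients(Z, scheme)$weights)
      expect_equal(got, brute_projection(z, scheme), tolerance = 1e-12)
    }
  }
})

test_that("projection output is symmetric with a zero diagonal", {
  set.seed(9)
  z <- random_counts(6, 8)
  A <- project_shared_patients(build_encounter_matrix(records_from_counts(z)))
  M <- as.matrix(A$weights)
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
})

test_that("binarization follows the threshold rule in both modes", {
  W <- matrix(c(0, 1, 100,
                1, 0, 0,
                100, 0, 0), 3, 3)
  A <- as_shared_patient_network(W)
  B0 <- binarize(A, 0)
  expect_equal(as.numeric(B0$edges[1, 2]), 1)  # any sharing at a_low = 0
  # strict inequality: a_ij = 100 at a_low = 100 is not an edge
  Bs <- binarize(A, 100, mode = "strict")
  expect_equal(as.numeric(Bs$edges[1, 3]), 0)
  Bi <- binarize(A, 100, mode = "inclusive")
  expect_equal(as.numeric(Bi$edges[1, 3]), 1)
  expect_error(binarize(A, -1), "a_low")

  # binarize(A, 0) edges coincide with nonzero off-diagonal weights
  set.seed(10)
  z <- random_counts(6, 10)
  Ar <- project_shared_patients(build_encounter_matrix(records_from_counts(z)))
  expect_equal(as.matrix(binarize(Ar, 0)$edges) > 0,
               as.matrix(Ar$weights) > 0)
})

test_that("edge sets are nested as the threshold grows", {
  set.seed(11)
  W <- matrix(0, 8, 8)
  W[upper.tri(W)] <- rpois(28, 200)
  W <- W + t(W)
  A <- as_shared_patient_network(W)
  cuts <- c(1, 10, 50, 100, 500, 1000)
  prev <- NULL
  for (a in cuts) {
    E <- as.matrix(binarize(A, a)$edges)
    if (!is.null(prev)) expect_true(all(E <= prev))
    prev <- E
  }
})

test_that("physician attribution tallies volumes with a lexicographic tie-break", {
  recs <- data.frame(
    physician_id = c(rep("p1", 12), rep("p2", 10)),
    patient_id = paste0("t", 1:22),
    hospital_id = c(rep("h1", 10), rep("h2", 2), rep("h2", 5), rep("h1", 5)),
    date = as.Date("2019-05-01"))
  att <- attribute_physicians(recs)
  expect_equal(att$primary_hospital_id[att$physician_id == "p1"], "h1")
  expect_equal(att$n_sites[att$physician_id == "p1"], 2L)
  expect_equal(att$n_nonprimary[att$physician_id == "p1"], 1L)
  # 5/5 tie for p2 resolves to the lexicographically smallest hospital
  expect_equal(att$primary_hospital_id[att$physician_id == "p2"], "h1")
  V <- attr(att, "volumes")
  expect_equal(unname(rowSums(V)),
               as.numeric(table(recs$physician_id)[att$physician_id]))
})

test_that("hospital network counts physicians billing at both hospitals", {
  recs <- data.frame(physician_id = "p1", patient_id = c("t1", "t2"),
                     hospital_id = c("h1", "h2"),
                     date = as.Date("2020-06-01"))
  hn <- build_hospital_network(recs)
  expect_equal(hn$edges["h1", "h2"], 1)

  single <- data.frame(physician_id = c("p1", "p2"),
                       patient_id = c("t1", "t2"),
                       hospital_id = c("h1", "h2"),
                       date = as.Date("2020-06-01"))
  expect_true(all(build_hospital_network(single)$edges == 0))

  span3 <- do.call(rbind, lapply(c("p1", "p2", "p3"), function(p)
    data.frame(physician_id = p, patient_id = paste0(p, c("a", "b")),
               hospital_id = c("h1", "h2"), date = as.Date("2020-06-01"))))
  expect_equal(build_hospital_network(span3)$edges["h1", "h2"], 3)

  expect_error(build_hospital_network(recs,
                                      window = c("2021-01-01", "2020-01-01")),
               "after")
})

test_that("networks round-trip through edge-list and GraphML exports", {
  set.seed(12)
  B <- as_binary_network(random_adjacency(6, 0.5))
  elist <- withr::local_tempfile(fileext = ".csv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  n_edges <- write_edge_list(B, elist)
  expect_equal(n_edges, sum(as.matrix(B$edges)) / 2)
  df <- read.csv(elist)
  expect_identical(names(df), c("source", "target", "weight"))
  write_graphml(B, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), n_edges)
})
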