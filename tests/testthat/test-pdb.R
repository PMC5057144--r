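# PDB-dialect serialization of wire models.

random_model <- function(n_traces, nodes_per_trace = 3, seed = 1) {
  set.seed(seed)
  nodes <- list(); conns <- list(); off <- 0L
  for (k in seq_len(n_traces)) {
    n <- nodes_per_trace
    nodes[[k]] <- tibble::tibble(
      trace = k, name = sprintf("%04d", seq_len(n)),
      x = round(runif(n, 0, 1100), 3), y = round(runif(n, 0, 1100), 3),
      z = round(runif(n, 0, 460), 3), diameter = round(runif(n, 3, 18), 2))
    conns[[k]] <- cbind(off + seq_len(n - 1), off + 2:n)
    off <- off + n
  }
  wire_model(do.call(rbind, nodes), do.call(rbind, conns))
}

test_that("write -> read -> write round-trips byte-identically", {
  m <- random_model(12, 5, seed = 3)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_model(m, f1)
  m2 <- read_pdb_model(f1)
  write_pdb_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(file.size(f1), file.size(f2))
  expect_equal(n_traces(m2), 12)
  expect_equal(m2$nodes$x, m$nodes$x, tolerance = 1e-9)  # 3-decimal fields
  expect_identical(m2$connections, m$connections)
})

test_that("a 488-trace model keeps its trace count through serialization", {
  m <- random_model(488, 2, seed = 8)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_model(m, f)
  lines <- readLines(f)
  het <- lines[startsWith(lines, "HETATM")]
  ids <- unique(paste(substr(het, 22, 22), trimws(substr(het, 23, 26))))
  expect_length(ids, 488)
  expect_equal(n_traces(read_pdb_model(f)), 488)
})

test_that("degenerate and malformed inputs behave", {
  single <- wire_model(tibble::tibble(trace = 1L, name = "0001", x = 1.5,
                                      y = 2.5, z = 3.5, diameter = 4),
                       NULL)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_model(single, f)
  lines <- readLines(f)
  expect_length(grep("^HETATM", lines), 1)
  expect_length(grep("^CONECT", lines), 0)
  expect_equal(n_traces(read_pdb_model(f)), 1)

  # empty model round trip
  fe <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_model(wire_model(), fe)
  expect_equal(n_traces(read_pdb_model(fe)), 0)

  # malformed coordinate field: error carries the line number
  bad <- lines
  nb <- grep("^HETATM", bad)[1]
  substr(bad[nb], 31, 38) <- "  xx.yyy"
  fb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, fb)
  err <- tryCatch(read_pdb_model(fb), error = function(e) e)
  expect_s3_class(err, "axotomo_parse_error")
  expect_match(conditionMessage(err), sprintf("line %d", nb))

  # coordinate overflow refuses to write
  big <- single
  big$nodes$x <- 123456.7
  expect_error(write_pdb_model(big, withr::local_tempfile()),
               class = "axotomo_overflow_error")
})

test_that("SWC export writes one row per node with tree parents", {
  m <- random_model(3, 4, seed = 2)
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc_model(m, f)
  rows <- read.table(f, comment.char = "#")
  expect_equal(nrow(rows), nrow(m$nodes))
  expect_equal(sum(rows$V7 == -1), 3)          # one root per trace
  expect_equal(rows$V6, m$nodes$diameter / 2)  # radius column
})
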