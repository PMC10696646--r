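test_that("ring buffer matches a list-slice oracle on arbitrary push sequences", {
  set.seed(41)
  for (rep in 1:10) {
    cap <- sample(3:50, 1)
    buf <- sample_buffer(cap)
    stream <- numeric(0)
    for (step in 1:30) {
      chunk <- rnorm(sample(0:7, 1))
      stream <- c(stream, chunk)
      if (length(chunk)) buffer_push(buf, chunk)
      expect_identical(buf$total_pushed, length(stream))
      expect_equal(buffer_contents(buf),
                   utils::tail(stream, cap))  # slice oracle
    }
  }
})

test_that("buffer holds exactly the last n samples after overflow", {
  buf <- sample_buffer(180)
  buffer_push(buf, seq_len(183))  # sample values 1..183 = stream indices 0..182
  expect_identical(buf$total_pushed, 183L)
  expect_equal(buffer_contents(buf), 4:183)  # 0-based stream samples 3..182
})

test_that("the simulator pushes every sample at the adjusted period", {
  rec <- make_test_record(1000, c(500L))
  s <- simulate_stream(rec, capacity = 180, period_factor = 0.9)
  expect_identical(s$total_pushed, 1000L)  # conservation
  expect_equal(s$period, 0.9 / 360)        # 0.0025 s between pushes
  expect_equal(buffer_contents(s$buffer), rec$signal[1, 821:1000])

  # wall-clock mode on a short record behaves identically in content
  rec2 <- make_test_record(40)
  s2 <- simulate_stream(rec2, capacity = 10, virtual_time = FALSE)
  expect_identical(s2$total_pushed, 40L)
  expect_equal(buffer_contents(s2$buffer), rec2$signal[1, 31:40])
})

test_that("the center check accepts centered beats and rejects off-center ones", {
  tmpl <- preset_templates("N")$N
  beat <- as.numeric(render_beat(tmpl, 360))
  n <- 180
  pad <- function(shift) {
    # place the beat peak at index n/2 + shift (0-based)
    x <- rep(0, n)
    pk <- attr(render_beat(tmpl, 360), "peak")
    start <- n / 2 + shift - pk
    ix <- start + seq_along(beat)
    keep <- ix >= 1 & ix <= n
    x[ix[keep]] <- beat[keep]
    x
  }
  expect_true(check_center(pad(0)))
  expect_true(check_center(pad(10)))   # inside the n/8 = 22 tolerance
  expect_false(check_center(pad(45)))  # shifted by n/4: rejected
  expect_false(check_center(pad(-45)))
  # flat signal: argmax ties break to index 0, far off-center -> reject
  expect_false(check_center(rep(0, n)))
  # tolerance is configurable
  expect_true(check_center(pad(45), tolerance = 50))
})

test_that("virtual-time accounting is exact for stub classifier costs", {
  stub <- function(samples) list(label = "N", confidence = 1)
  n <- 180
  # zero-latency detector misses nothing
  rec <- make_test_record(400)
  rep0 <- run_workflow(rec, stub, n = n, use_check_center = FALSE,
                       h = 8, virtual_time = TRUE)
  expect_gt(nrow(rep0$records), 0)
  expect_true(all(rep0$records$samples_missed == 0))
  expect_identical(rep0$totals$total_pushed, 400L)  # conservation

  # a stub costing exactly 8 sample periods misses exactly 8 per classification
  k <- 8
  total <- n + 9 * 40  # busy periods complete within the stream
  rec <- make_test_record(total)
  repk <- run_workflow(rec, stub, n = n, use_check_center = FALSE, h = 8,
                       virtual_time = TRUE,
                       virtual_costs = list(classify = k))
  expect_identical(nrow(repk$records), 40L)
  expect_true(all(repk$records$samples_missed == k))
  # spans are n samples wide in stream coordinates
  expect_true(all(repk$records$end - repk$records$start == n))
  expect_identical(repk$records$start[1], 0L)
})

test_that("costs of every stage count toward missed samples", {
  stub <- function(samples) list(label = "N", confidence = 1)
  n <- 180
  total <- n + (3 + 2 + 5 + 1) * 20
  rec <- make_test_record(total)
  rep <- run_workflow(rec, stub, n = n, use_check_center = TRUE, h = 8,
                      tolerance = n,  # accept everything
                      virtual_time = TRUE,
                      virtual_costs = list(check = 3, convert = 2, classify = 5))
  expect_true(all(rep$records$samples_missed == 10))
})

test_that("with the center check on, every classified window passes it", {
  cfg <- synthesis_config(duration = 15, noise_sd = 0.01, seed = 77)
  rec <- generate_record(cfg)
  stub <- function(samples) list(label = "N", confidence = 1)
  rep <- run_workflow(rec, stub, n = 180, h = 64, use_check_center = TRUE,
                      virtual_time = TRUE,
                      virtual_costs = list(classify = 40))
  expect_gt(nrow(rep$records), 0)
  sig <- rec$signal[1, ]
  for (i in seq_len(nrow(rep$records))) {
    win <- sig[(rep$records$start[i] + 1):(rep$records$end[i])]
    expect_true(check_center(win))
  }
  # rejected states exist: fewer classifications than buffer states
  expect_lt(nrow(rep$records), ncol(rec$signal) - 180)
})

test_that("workflow validates geometry and classifies with a trained network", {
  rec <- generate_record(synthesis_config(duration = 10, seed = 5))
  m <- build_proposed()
  expect_error(run_workflow(rec, m, n = 128, h = 128), "geometry")

  # untrained network, big virtual cost: runs end to end and reports labels
  rep <- run_workflow(rec, m, use_check_center = TRUE, virtual_time = TRUE,
                      virtual_costs = list(classify = 300))
  expect_true(all(rep$records$label %in% class_labels()))
  expect_true(all(rep$records$confidence >= 0 & rep$records$confidence <= 1))
  expect_true(all(rep$records$samples_missed >= 0))
})

test_that("stream reports serialize with location spans and percent confidence", {
  stub <- function(samples) list(label = "N", confidence = 0.9999)
  rec <- make_test_record(450)
  rep <- run_workflow(rec, stub, n = 180, h = 8, use_check_center = FALSE,
                      virtual_time = TRUE, virtual_costs = list(classify = 89))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_stream_report(rep, csv_path = csv, json_path = js)
  tab <- read.csv(csv)
  expect_identical(names(tab), c("id", "location", "classification", "confidence"))
  expect_true(all(grepl("^[0-9]+-[0-9]+$", tab$location)))
  expect_true(all(grepl("%$", tab$confidence)))
  spans <- t(vapply(strsplit(tab$location, "-"),
                    function(p) as.numeric(p), numeric(2)))
  expect_true(all(spans[, 2] - spans[, 1] == 180))
  j <- jsonlite::read_json(js)
  expect_true(all(c("mean_missed", "mean_t_check", "mean_t_convert",
                    "mean_t_classify", "mean_confidence",
                    "weighted_confidence") %in% names(j)))
})
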