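# Morphometrics: elongation factor, perimeter, migration statistics,
# Rel-VEcad-C, plaque metrics and the pole/lateral boundary partition.

regularPolygon <- function(n, r, cx = 0, cy = 0, stretch = 1) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + stretch * r * cos(t), cy + r * sin(t))
}

test_that("elongation factor: circle, ellipse, rectangle closed form", {
  circle <- CellOutline(regularPolygon(180, 10))
  expect_equal(elongationFactor(circle), 1, tolerance = 1e-6)
  expect_equal(elongationFactor(Ellipse(0, 0, 4, 2)), 2)

  rect <- CellOutline(rbind(c(0, 0), c(50, 0), c(50, 10), c(0, 10)))
  # continuous rectangle second moments: aspect = L / W
  expect_equal(elongationFactor(rect), 5, tolerance = 0.05 * 5)

  # invariance under rotation and uniform scaling
  stretched <- regularPolygon(120, 10, stretch = 2.5)
  ef0 <- elongationFactor(CellOutline(stretched))
  for (phi in c(0.4, 1.1, 2.9)) {
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    rot <- stretched %*% R * 3.7
    expect_equal(elongationFactor(CellOutline(rot)), ef0,
                 tolerance = 0.01 * ef0)
  }
  expect_error(outlineEllipse(CellOutline(rbind(c(0, 0), c(1, 0),
                                                c(2, 0.001)))),
               class = "degenerateGeometry")
})

test_that("perimeter: square, near-circle closed form, calibration linearity", {
  sq <- CellOutline(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
                    pixelSize = 0.5)
  expect_equal(polygonPerimeter(sq), 20)

  # regular 360-gon approximates 2*pi*r to 0.1% (closed form 2*n*r*sin(pi/n))
  r <- 12
  p360 <- CellOutline(regularPolygon(360, r))
  expect_equal(polygonPerimeter(p360), 2 * 360 * r * sin(pi / 360),
               tolerance = 1e-9)
  expect_lt(abs(polygonPerimeter(p360) - 2 * pi * r) / (2 * pi * r), 0.001)

  sq2 <- CellOutline(sq@vertices, pixelSize = 1.7)
  expect_equal(polygonPerimeter(sq2), 20 / 0.5 * 1.7)
})

test_that("migration summary: stationarity, 3-4-5 path, triangle inequality", {
  st <- migrationSummary(rbind(c(5, 5), c(5, 5), c(5, 5)), 1, 600)
  expect_equal(st$accumulated_um, 0)
  expect_equal(st$euclidean_um, 0)
  expect_equal(st$mean_velocity_um_h, 0)
  expect_true(is.na(st$directionality))

  tri <- migrationSummary(rbind(c(0, 0), c(3, 0), c(3, 4)), 1, 1800)
  expect_equal(tri$accumulated_um, 7)
  expect_equal(tri$euclidean_um, 5)
  expect_equal(tri$mean_velocity_um_h, 7 / 1)   # 2 steps x 1800 s = 1 h

  set.seed(8)
  for (rep in 1:25) {
    path <- matrix(rnorm(20), ncol = 2)
    msum <- migrationSummary(path, runif(1, 0.3, 2), 600)
    expect_gte(msum$accumulated_um, msum$euclidean_um)
  }
  expect_error(migrationSummary(matrix(c(1, 1), 1, 2), 1, 60),
               class = "invalidInput")
})

test_that("Rel-VEcad-C: uniform ribbon, intensity linearity", {
  # straight ribbon of width 3 px, uniform intensity c: the value is
  # c * w / pixelSize, independent of ribbon length
  img <- matrix(0, 30, 60)
  img[14:16, 6:55] <- 7
  mask <- img > 0
  px <- 0.5
  for (lenPx in c(50, 30)) {
    m2 <- mask; m2[, (5 + lenPx + 1):60] <- FALSE
    i2 <- img; i2[!m2] <- 0
    r <- relVEcadC(i2, m2, lengthUm = lenPx * px, pixelSize = px)
    expect_equal(r$rel_vecad_c, 7 * 3 / px, tolerance = 1e-10)
  }
  r1 <- relVEcadC(img, mask, lengthUm = 25, pixelSize = px)
  r2 <- relVEcadC(img * 2, mask, lengthUm = 25, pixelSize = px)
  expect_equal(r2$rel_vecad_c, 2 * r1$rel_vecad_c)

  # constant offset removed by background subtraction
  r3 <- relVEcadC(img + 11, mask, lengthUm = 25, pixelSize = px,
                  backgroundSubtract = TRUE)
  expect_equal(r3$rel_vecad_c, r1$rel_vecad_c, tolerance = 1e-10)

  expect_error(relVEcadC(img, mask, lengthUm = 0, pixelSize = px),
               class = "invalidInput")
})

test_that("total VE-cadherin estimate is the perimeter x density product", {
  expect_equal(totalVEcadEstimate(0, 5), 0)
  expect_equal(totalVEcadEstimate(100, 2), 200)
  expect_error(totalVEcadEstimate(-1, 2), class = "invalidInput")
})

test_that("plaque metrics: counts, areas, 8-connectivity", {
  expect_equal(plaqueMetrics(matrix(FALSE, 10, 10))$count, 0L)

  m <- matrix(FALSE, 40, 40)
  m[3:8, 3:7] <- TRUE          # 30 px
  m[20:26, 20:29] <- TRUE      # 70 px
  pm <- plaqueMetrics(m, pixelSize = 1, minAreaUm2 = 10)
  expect_equal(pm$count, 2L)
  expect_equal(sort(pm$areas_um2), c(30, 70))
  # min-area filter removes the small one
  expect_equal(plaqueMetrics(m, 1, minAreaUm2 = 50)$count, 1L)

  # diagonal-touching pixels: one component under 8-connectivity
  d <- matrix(FALSE, 6, 6)
  d[2, 2] <- TRUE; d[3, 3] <- TRUE; d[4, 4] <- TRUE
  pmd <- plaqueMetrics(d, 1, 0)
  expect_equal(pmd$count, 1L)
  expect_equal(max(oracleFloodLabel(d)), 1L)
})

test_that("pole/lateral partition: rectangle ends, limits, analytic ellipse", {
  rect <- CellOutline(rbind(c(0, 0), c(60, 0), c(60, 10), c(0, 10)))
  part <- poleLateralPartition(rect, halfAngleDeg = 45)
  pts <- part$points
  ends <- pts[, 1] < 5 | pts[, 1] > 55
  expect_true(all(part$zone[ends] == "pole"))
  mid <- pts[, 1] > 25 & pts[, 1] < 35
  expect_true(all(part$zone[mid] == "lateral"))

  # pole fraction vanishes with the half-angle
  fr <- vapply(c(45, 20, 5, 1), function(ha)
    poleLateralPartition(rect, halfAngleDeg = ha)$poleFraction, numeric(1))
  expect_true(all(diff(fr) < 0))
  expect_lt(fr[4], 0.05)

  # ellipse a/b = 3: pole arc fraction matches a dense parametric
  # arc-length integral of the boundary
  t <- seq(0, 2 * pi, length.out = 2001)[-2001]
  a <- 30; b <- 10
  ell <- CellOutline(cbind(a * cos(t), b * sin(t)))
  got <- poleLateralPartition(ell, halfAngleDeg = 30)$poleFraction
  tt <- seq(0, 2 * pi, length.out = 20001)
  xs <- a * cos(tt); ys <- b * sin(tt)
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  midAng <- atan2((ys[-1] + ys[-length(ys)]) / 2,
                  (xs[-1] + xs[-length(xs)]) / 2)
  dd <- abs(midAng - pi * round(midAng / pi))
  oracle <- sum(seg[dd <= pi / 6]) / sum(seg)
  expect_equal(got, oracle, tolerance = 0.02)

  circ <- CellOutline(regularPolygon(90, 10))
  expect_error(poleLateralPartition(circ), class = "notApplicable")
})
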