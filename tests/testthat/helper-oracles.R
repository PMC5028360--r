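# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# brute-force Otsu: recompute the within-class variance from the raw
# quantized values for every candidate threshold
otsu_bruteforce <- function(values255) {
  best_t <- NA_integer_; best_obj <- Inf
  n <- length(values255)
  for (t in 0:254) {
    c1 <- values255[values255 <= t]
    c2 <- values255[values255 > t]
    if (length(c1) == 0 || length(c2) == 0) next
    v1 <- if (length(c1) > 1) mean((c1 - mean(c1))^2) else 0
    v2 <- if (length(c2) > 1) mean((c2 - mean(c2))^2) else 0
    obj <- length(c1) / n * v1 + length(c2) / n * v2
    if (obj < best_obj) { best_obj <- obj; best_t <- t }
  }
  list(threshold = best_t, objective = best_obj)
}

# pixel-by-pixel loop over a mask pair
metrics_pixel_loop <- function(pred, gt) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    if (pred[i, j] && gt[i, j]) tp <- tp + 1L
    else if (pred[i, j] && !gt[i, j]) fp <- fp + 1L
    else if (!pred[i, j] && gt[i, j]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  fallout <- if (fp + tn > 0) fp / (fp + tn) else 0
  tnr <- if (tn + fp > 0) tn / (tn + fp) else 0
  tpr <- tp / (tp + fn); fnr <- fn / (tp + fn)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       tdr = tp / (tp + fn), fpr = fp / (tp + fn), fallout = fallout,
       fnr = fnr, tnr = tnr, tpr = tpr,
       ep = (fallout + fnr) / (tpr + fallout + tnr + fnr),
       dice = 2 * tp / ((tp + fp) + (tp + fn)))
}

# dark line through the image center at the given angle; angle measured
# from the column axis toward increasing row index
render_line_image <- function(h = 128, w = 128, angle, bg = 200, fg = 60,
                              thick = 2) {
  m <- matrix(bg, h, w)
  th <- angle * pi / 180
  dir <- c(sin(th), cos(th)); ctr <- c(h / 2, w / 2)
  half <- thick %/% 2
  for (t in seq(-max(h, w), max(h, w), by = 0.25)) {
    p <- round(ctr + t * dir)
    r0 <- max(1, p[1] - half); r1 <- min(h, p[1] + half)
    c0 <- max(1, p[2] - half); c1 <- min(w, p[2] + half)
    if (r0 <= r1 && c0 <= c1 && p[1] >= 1 && p[1] <= h && p[2] >= 1 && p[2] <= w)
      m[r0:r1, c0:c1] <- fg
  }
  gray_image(m)
}

# random blobby binary mask (threshold of smoothed noise)
random_mask <- function(h, w, p_fore = 0.5) {
  m <- matrix(stats::rnorm(h * w), h, w)
  m <- EBImage::gblur(m, sigma = 2)
  matrix(as.numeric(m) > stats::quantile(as.numeric(m), 1 - p_fore), h, w)
}

# reference 1-D analysis coefficients (half-sample symmetric extension)
# for x = (12, 45, 3, 78, 56, 23, 91, 34, 67, 8, 50, 29), computed with an
# independent wavelet implementation and frozen
dwt_reference <- list(
  x = c(12, 45, 3, 78, 56, 23, 91, 34, 67, 8, 50, 29),
  "haar" = list(
    cA = c(40.305086527633, 57.275649276110, 55.861435713737, 88.388347648318, 53.033008588991, 55.861435713737),
    cD = c(-23.334523779156, -53.033008588991, 23.334523779156, 40.305086527633, 41.719300090006, 14.849242404917)),
  "db4" = list(
    cA = c(86.326089361688, 46.583334611330, 28.698691797240, 27.509982450805, 77.281683933911, 74.853554990542, 79.280702442237, 47.557692865183, 49.869547934065),
    cD = c(-9.737138267253, -41.843335967288, -6.644749072866, 54.215178631247, 25.487479530983, 29.955398824502, -9.002805742599, -36.079120018158, -30.389815987353)),
  "sym4" = list(
    cA = c(31.564342480622, 27.624076760245, 51.335029541739, 73.936480244984, 87.875549757222, 56.765252572750, 48.209083123679, 48.610984968008, 45.129235756143),
    cD = c(49.312966118735, 12.415115110464, -26.064906348205, -44.054816856587, 40.841201378181, 33.580478674320, 36.817055074229, 8.072364682344, -23.015116924083)),
  "bior6.8" = list(
    cA = c(87.663191177507, 67.548911472233, 78.249551826250, 29.007098375520, 28.746918417149, 49.893916514639, 76.503224528084, 83.735333892298, 61.171682413144, 45.540448323875, 50.626967436312, 42.762682560045, 87.663191177507, 67.548911472233),
    cD = c(-46.747267683485, -3.574928117057, 47.674661560739, 9.472718037280, -30.139028566621, -38.954810577529, 43.107266600489, 32.037789697844, 35.780780709243, 7.781015491406, -25.356209095747, -31.081988056569, -46.747267683485, -3.574928117057)),
  "cdf97" = list(
    cA = c(80.538419999717, 32.651030868147, 29.571581877342, 45.766126450255, 76.574460674590, 85.454594966476, 59.358936943436, 47.720558817526, 50.158835958169, 43.907927510094),
    cD = c(49.567912262461, 11.094874729081, -32.066848200601, -40.715058472893, 43.363887974467, 33.670318598468, 37.427678429618, 7.682776732925, -25.469948761410, -32.887474837666))
)
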