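# cropsuit

Weakly supervised multi-crop land-suitability modelling in R: learn
*per-pixel* crop yields when the only labels are *district-level* mean
yields.

## The problem

Agricultural statistics agencies publish crop yields (bushels/acre) as one
number per crop, district and year. Land-suitability mapping needs the
opposite resolution — for every pixel of a landscape, how well would each
crop grow there, including where it is not currently cultivated? Pixel
yields are never observed, so ordinary supervised regression does not
apply; and because a field grows a single crop per season, no location
ever has labels for more than one crop at a time.

## The method

A multilayer perceptron (default $16 \to 256 \to 512 \to 256 \to C$, ReLU,
dropout on hidden layers) maps each pixel's 16 soil–climate–landscape
covariates to $C$ per-crop yield predictions $\hat y_i$. Supervision is
attached through an **averaging head** over the group of pixels sharing a
crop $c$, district $d$ and year $t$:

$$\hat y_{c,d,t} = \frac{1}{n_{c,d,t}} \sum_{i=1}^{n_{c,d,t}} \hat y_{i,c}$$

and an **indicator-masked L1 loss** that compares only the observed crop:

$$\mathrm{Loss} = I_{\mathrm{observed}}^{\top} E, \qquad
E_c = |\hat y_{c,d,t} - y_{c,d,t}|,$$

so each example updates the observed crop's output head and the shared
layers — the mechanism by which correlated crops borrow strength from one
another. Training uses Adam on standardized features and labels.
Evaluation is district-held-out k-fold cross-validation with per-crop MAE,
fold SD, evaluable-fold counts and relative error (MAE / observed yield
range); a per-crop single-output baseline with the same architecture
quantifies the multi-crop advantage as the ratio of the two MAEs.

The package also generates complete synthetic landscapes with known
ground truth (spatially autocorrelated covariates, Voronoi districts,
correlated per-crop response functions, suitability-biased crop placement,
district labels equal to group means plus noise), so the whole pipeline is
testable end to end. See the vignette
(`vignettes/multicrop-suitability.Rmd`) for the model, generator and
design notes.

## Worked example

```r
library(cropsuit)

# a synthetic study area: 32x32 pixels, 6 crops, 12 districts, 3 years
b <- simulate_bundle(height = 32, width = 32, n_crops = 6,
                     n_districts = 12, years = 2013:2015,
                     cultivated_fraction = 0.5, seed = 42)

# group pixels into (crop, district, year) examples with district labels
ex <- build_examples(b$grids, b$partition, b$assignments, b$yields)
length(ex)          # 215 aggregated examples
range(b$yields$yield)  # 35.21 .. 89.60 bushels/acre

# district-held-out cross-validation of the multi-crop model
plan <- split_by_district(ex, k = 3, districts_per_fold = 3, seed = 1)
cfg <- model_config(input_dim = 16, hidden_dims = 32, output_dim = 6,
                    dropout_rate = 0, epochs = 200, batch_groups = 16,
                    seed = 1)
cv <- crossval(ex, plan, cfg, mode = "multi")
cv$summary
#>    crop mae_mean    mae_sd n_val_sets relative_error_pct
#> 1 crop1 3.250317 0.9959305          3           11.38435
#> 2 crop2 3.806508 0.9569194          3           14.85278
#> 3 crop3 3.753065 1.5525744          3           16.31804
#> 4 crop4 3.304529 0.2016493          3           17.77795
#> 5 crop5 3.771803 0.3459974          3           16.60278
#> 6 crop6 3.977992 0.3208601          3           14.57208

# suitability maps: per-year prediction, averaged over years
fit <- train(ex, cfg, crop_names = b$truth$crop_names)
maps <- predict_suitability(fit, b$grids)
summarize_by_zone(maps[["crop1"]], b$partition)[1:3, ]
#>   zone mean_yield n_pixels
#> 1    1   75.30138       58
#> 2    2   72.03280      206
#> 3    3   70.19803       59
export_map(maps[["crop1"]], "crop1_suitability.tif")  # clamps negatives to 0
```

Each `cv$summary` row is a crop's held-out error averaged over folds:
e.g. crop1 is predicted in unseen districts to within about 3.3
bushels/acre, roughly 11% of its observed yield range. The zone summary
averages a crop's predicted suitability over district polygons, the same
reduction used for growing-season-zone comparisons.

A command-line interface wrapping the same functions lives in
`inst/cli/cropsuit.R` (subcommands `simulate`, `train`, `crossval`,
`predict-map`, `compare`).

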