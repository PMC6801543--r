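# Regrouping of the 17 IGBP-style land-cover classes onto the five
# runoff weight classes.  Editable: the five targets must match the names
# in defaultLanduseWeights().
"Evergreen needleleaf forest": "Forest"
"Evergreen broadleaf forest": "Forest"
"Deciduous needleleaf forest": "Forest"
"Deciduous broadleaf forest": "Forest"
"Mixed forest": "Forest"
"Closed shrublands": "Grass/scrub/woodland"
"Open shrublands": "Grass/scrub/woodland"
"Woody savannas": "Grass/scrub/woodland"
"Savannas": "Grass/scrub/woodland"
"Grasslands": "Grass/scrub/woodland"
"Permanent wetlands": "Grass/scrub/woodland"
"Croplands": "Irrigated and rain-fed cultivated land"
"Urban and built-up": "Built-up land"
"Cropland/natural vegetation mosaic": "Irrigated and rain-fed cultivated land"
"Snow and ice": "Barren/very sparsely vegetated land"
"Barren or sparsely vegetated": "Barren/very sparsely vegetated land"
"Water bodies": "Barren/very sparsely vegetated land"
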