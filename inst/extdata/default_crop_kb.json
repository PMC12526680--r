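{
  "comment": "Illustrative per-crop optimum temperature (degC) and soil pH with spreads. Working defaults for the 22-class crop-recommendation schema; NOT validated agronomic reference values - supply your own table for real analyses.",
  "crops": [
    {"label": "apple",       "mu_temp": 21.0, "sigma_temp": 2.5, "mu_ph": 6.10, "sigma_ph": 0.40},
    {"label": "banana",      "mu_temp": 27.0, "sigma_temp": 2.5, "mu_ph": 6.00, "sigma_ph": 0.50},
    {"label": "blackgram",   "mu_temp": 29.0, "sigma_temp": 3.0, "mu_ph": 7.10, "sigma_ph": 0.50},
    {"label": "chickpea",    "mu_temp": 18.5, "sigma_temp": 3.0, "mu_ph": 7.30, "sigma_ph": 0.50},
    {"label": "coconut",     "mu_temp": 27.0, "sigma_temp": 2.0, "mu_ph": 5.90, "sigma_ph": 0.40},
    {"label": "coffee",      "mu_temp": 25.5, "sigma_temp": 2.0, "mu_ph": 6.80, "sigma_ph": 0.40},
    {"label": "cotton",      "mu_temp": 24.0, "sigma_temp": 2.5, "mu_ph": 6.90, "sigma_ph": 0.50},
    {"label": "grapes",      "mu_temp": 23.5, "sigma_temp": 3.0, "mu_ph": 6.25, "sigma_ph": 0.45},
    {"label": "jute",        "mu_temp": 25.0, "sigma_temp": 2.5, "mu_ph": 6.70, "sigma_ph": 0.40},
    {"label": "kidneybeans", "mu_temp": 20.0, "sigma_temp": 3.0, "mu_ph": 5.80, "sigma_ph": 0.45},
    {"label": "lentil",      "mu_temp": 22.0, "sigma_temp": 3.0, "mu_ph": 6.90, "sigma_ph": 0.50},
    {"label": "maize",       "mu_temp": 22.5, "sigma_temp": 3.0, "mu_ph": 6.20, "sigma_ph": 0.50},
    {"label": "mango",       "mu_temp": 31.0, "sigma_temp": 3.0, "mu_ph": 5.70, "sigma_ph": 0.45},
    {"label": "mothbeans",   "mu_temp": 28.5, "sigma_temp": 3.5, "mu_ph": 7.00, "sigma_ph": 0.70},
    {"label": "mungbean",    "mu_temp": 28.5, "sigma_temp": 3.0, "mu_ph": 6.70, "sigma_ph": 0.50},
    {"label": "muskmelon",   "mu_temp": 28.5, "sigma_temp": 2.5, "mu_ph": 6.40, "sigma_ph": 0.45},
    {"label": "orange",      "mu_temp": 23.0, "sigma_temp": 3.0, "mu_ph": 6.50, "sigma_ph": 0.50},
    {"label": "papaya",      "mu_temp": 32.0, "sigma_temp": 3.0, "mu_ph": 6.55, "sigma_ph": 0.50},
    {"label": "pigeonpeas",  "mu_temp": 27.5, "sigma_temp": 3.5, "mu_ph": 6.10, "sigma_ph": 0.60},
    {"label": "pomegranate", "mu_temp": 21.5, "sigma_temp": 2.5, "mu_ph": 6.45, "sigma_ph": 0.40},
    {"label": "rice",        "mu_temp": 25.0, "sigma_temp": 3.0, "mu_ph": 6.00, "sigma_ph": 0.50},
    {"label": "watermelon",  "mu_temp": 26.0, "sigma_temp": 2.5, "mu_ph": 6.35, "sigma_ph": 0.45}
  ]
}
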