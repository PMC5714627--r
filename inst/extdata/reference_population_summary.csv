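statistic,reference_value
phantom_rpm_cv_vs_itv_true_diff_r,0.74
phantom_bellows_cv_vs_itv_true_diff_r,0.63
phantom_bpm_vs_itv_true_diff_r,-0.60
phantom_mean_volume_change_percent,-0.29
phantom_mean_itv_true_diff_bellows_percent,12.60
phantom_mean_itv_true_diff_rpm_percent,12.39
phantom_mean_pearson_r,0.994
patient_mean_volume_change_percent,-0.293
patient_mean_overlap_index,0.994
patient_mean_dice,0.993
patient_mean_pearson_r,0.947
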