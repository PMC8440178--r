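disorder	measure	n_cases	n_controls
ADHD	thickness	2246	1934
ADHD	surface_area	2246	1934
ADHD	subcortical_volume	1713	1529
ASD	thickness	1571	1651
ASD	surface_area	1571	1651
ASD	subcortical_volume	1571	1651
BD	thickness	1837	2582
BD	surface_area	1820	2582
BD	subcortical_volume	1710	2594
Epilepsy	thickness	2149	1727
Epilepsy	subcortical_volume	2149	1727
MDD	thickness	1911	7663
MDD	surface_area	1902	7658
MDD	subcortical_volume	1728	7199
OCD	thickness	1498	1435
OCD	surface_area	1497	1433
OCD	subcortical_volume	1495	1472
SCZ	thickness	4474	5098
SCZ	surface_area	4434	5073
SCZ	subcortical_volume	2028	2540
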